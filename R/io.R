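#' Read a parameter configuration file
#'
#' YAML file with one entry per parameter. Each entry is either a bare number
#' (a value override) or a mapping with any of `value`, `fixed`, `lower`,
#' `upper`. Missing entries fall back to the package defaults
#' ([parameter_table()]); unknown keys are rejected; every resulting value is
#' validated against its bounds.
#'
#' @param path YAML file path.
#' @return list with `parameters` (a [kinetic_parameters()] set) and `table`
#'   (the merged parameter table with value/fixed/lower/upper).
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  tab <- parameter_table()
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), tab$name)
  if (length(unknown)) {
    stop("unknown parameter key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(raw)) {
    ent <- raw[[nm]]
    i <- match(nm, tab$name)
    if (is.numeric(ent) && length(ent) == 1L) {
      tab$value[i] <- ent
    } else if (is.list(ent)) {
      bad <- setdiff(names(ent), c("value", "fixed", "lower", "upper"))
      if (length(bad)) {
        stop("invalid field(s) for parameter ", nm, ": ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      if (!is.null(ent$value)) tab$value[i] <- as.numeric(ent$value)
      if (!is.null(ent$fixed)) tab$fixed[i] <- isTRUE(ent$fixed)
      if (!is.null(ent$lower)) tab$lower[i] <- as.numeric(ent$lower)
      if (!is.null(ent$upper)) tab$upper[i] <- as.numeric(ent$upper)
    } else {
      stop("parameter ", nm, " must be a number or a mapping", call. = FALSE)
    }
  }
  p <- do.call(kinetic_parameters, stats::setNames(as.list(tab$value),
                                                   tab$name))
  for (i in seq_len(nrow(tab))) {
    lo <- tab$lower[i]; hi <- tab$upper[i]
    if (!is.na(lo) && !is.na(hi) &&
        (tab$value[i] < lo - 1e-12 || tab$value[i] > hi + 1e-12)) {
      stop(sprintf("parameter %s = %g outside its range [%g, %g]",
                   tab$name[i], tab$value[i], lo, hi), call. = FALSE)
    }
  }
  list(parameters = p, table = tab)
}

#' Write a parameter configuration file
#'
#' Inverse of [load_parameters()]: writes every parameter with its value,
#' fixed flag and (where present) bounds. `load_parameters()` on the result
#' reproduces the same table.
#'
#' @param table a parameter table (as from [parameter_table()] or
#'   `load_parameters()$table`).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(table, path) {
  ents <- lapply(seq_len(nrow(table)), function(i) {
    ent <- list(value = table$value[i], fixed = table$fixed[i])
    if (!is.na(table$lower[i])) ent$lower <- table$lower[i]
    if (!is.na(table$upper[i])) ent$upper <- table$upper[i]
    ent
  })
  names(ents) <- table$name
  yaml::write_yaml(ents, path)
  invisible(path)
}

.obs_header <- c("t_h", "X_gL", "S_gL", "P_gL", "A_gL")

#' Write observations to a delimited text file
#'
#' CSV with header `t_h, X_gL, S_gL, P_gL, A_gL` (units in the suffixes) and
#' blank cells for missing values, preceded by `#`-prefixed metadata lines
#' (experiment id, feeding growth rate, initial amounts and volumes, lag).
#'
#' @param obs a [observations()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(id = obs$id, mu_F = obs$mu_F,
            X0_g = obs$init$X0, S0_g = obs$init$S0, P0_g = obs$init$P0,
            A0_g = obs$init$A0, V0_L = obs$init$V0, v0_L = obs$init$v0,
            t_lag_h = obs$t_lag)
  writeLines(sprintf("# %s = %s", names(meta), meta), con)
  df <- obs$data
  names(df) <- .obs_header
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Read observations from a delimited text file
#'
#' Counterpart of [write_observations()]; validates the header and the time
#' column (strictly increasing) and re-assembles the
#' [observations()] object from the metadata lines.
#'
#' @param path CSV path.
#' @return A `surfkin_observations` object.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "\\s*=\\s*")[[1]]
    if (length(kv) == 2L) meta[[kv[1]]] <- kv[2]
  }
  header_at <- which(!grepl("^#", lines))[1]
  header <- strsplit(lines[header_at], ",")[[1]]
  if (!identical(header, .obs_header)) {
    stop(sprintf("malformed header at line %d: expected '%s'", header_at,
                 paste(.obs_header, collapse = ",")), call. = FALSE)
  }
  body <- if (header_at < length(lines)) {
    lines[seq.int(header_at + 1L, length(lines))]
  } else {
    character(0)
  }
  if (!length(body)) stop("no data rows in ", path, call. = FALSE)
  df <- utils::read.csv(text = body, header = FALSE,
                        col.names = .obs_header, na.strings = "")
  if (any(diff(df$t_h) <= 0)) {
    stop("time column must be strictly increasing", call. = FALSE)
  }
  num <- function(key, default = NA_real_) {
    if (is.null(meta[[key]])) default else as.numeric(meta[[key]])
  }
  observations(id = if (is.null(meta$id)) basename(path) else meta$id,
               mu_F = num("mu_F"),
               times = df$t_h, X = df$X_gL, S = df$S_gL, P = df$P_gL,
               A = df$A_gL,
               init = list(X0 = num("X0_g"), S0 = num("S0_g"),
                           P0 = num("P0_g"), A0 = num("A0_g"),
                           V0 = num("V0_L"), v0 = num("v0_L")),
               t_lag = num("t_lag_h"))
}

#' Write a simulated trajectory to a delimited text file
#'
#' CSV with columns `t_h, X_g, S_g, P_g, A_g, V_L, v_L, X_gL, S_gL, P_gL,
#' A_gL, mu_S, mu_A, phase`.
#'
#' @param traj a `surfkin_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(t_h = traj$t, X_g = traj$X, S_g = traj$S, P_g = traj$P,
                   A_g = traj$A, V_L = traj$V, v_L = traj$v,
                   X_gL = traj$X_conc, S_gL = traj$S_conc,
                   P_gL = traj$P_conc, A_gL = traj$A_conc,
                   mu_S = traj$mu_S, mu_A = traj$mu_A, phase = traj$phase)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
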