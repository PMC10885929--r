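fmt17 <- function(x) sprintf("%.17g", x)

# CSV writer at 17 significant digits; paired with base R's correctly
# rounded strtod parsing this round-trips doubles bit-exactly.
write_csv17 <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) {
      out <- fmt17(col)
      out[is.na(col)] <- "NA"
      out
    } else {
      as.character(col)
    }
  })
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

read_csv_base <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

axes_uniform_spacing <- function(ax) {
  sp <- vapply(ax, function(v) {
    if (length(v) < 2) return(1)
    d <- diff(v)
    if (max(abs(d - d[1])) > 1e-9 * max(abs(d))) NA_real_ else d[1]
  }, numeric(1))
  if (anyNA(sp)) {
    stop("legacy-VTK structured-points output needs uniformly spaced axes; write CSV instead.",
         call. = FALSE)
  }
  sp
}

#' Write a velocity field
#'
#' Two dialects: legacy-VTK ASCII `STRUCTURED_POINTS` with a `VECTORS
#' velocity double` attribute (uniform grids only), and CSV with columns
#' `x, y, z, ux, uy, uz` (any grid; bit-exact archival format, values
#' written with 17 significant digits).
#'
#' @param field A [flow_field()].
#' @param path Output file path.
#' @param format `"vtk"` or `"csv"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_velocity_field <- function(field, path, format = guess_format(path)) {
  format <- match.arg(format, c("vtk", "csv"))
  if (format == "csv") {
    df <- tibble::as_tibble(field)[, c("x", "y", "z", "ux", "uy", "uz")]
    write_csv17(df, path)
    return(invisible(path))
  }
  ax <- field_axes(field)
  sp <- axes_uniform_spacing(ax)
  n <- vapply(ax, length, integer(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "hemocond velocity field",
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    paste("DIMENSIONS", n[1], n[2], n[3]),
    paste("ORIGIN", fmt17(ax$x[1]), fmt17(ax$y[1]), fmt17(ax$z[1])),
    paste("SPACING", fmt17(sp[1]), fmt17(sp[2]), fmt17(sp[3])),
    paste("POINT_DATA", nrow(field)),
    "VECTORS velocity double"
  ), con)
  writeLines(paste(fmt17(field$ux), fmt17(field$uy), fmt17(field$uz)), con)
  invisible(path)
}

#' Read a velocity field
#'
#' Accepts the two dialects written by [write_velocity_field()]. CSV rows
#' may arrive in any order: they are keyed by coordinates and re-sorted
#' into grid order; the coordinates must form a complete structured
#' lattice. Missing columns and non-finite velocities are reported as
#' errors naming the offender.
#'
#' @param path Input file path.
#' @param format `"vtk"` or `"csv"`; default guessed from the extension.
#' @return A [flow_field()] (finite-difference gradient; no analytic
#'   closure survives serialisation).
#' @export
read_velocity_field <- function(path, format = guess_format(path)) {
  format <- match.arg(format, c("vtk", "csv"))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "csv") read_velocity_csv(path) else read_velocity_vtk(path)
}

read_velocity_csv <- function(path) {
  df <- read_csv_base(path)
  need <- c("x", "y", "z", "ux", "uy", "uz")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("CSV velocity field is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(as.matrix(df[, need])))) {
    stop("CSV velocity field contains non-finite values.", call. = FALSE)
  }
  axes <- list(x = sort(unique(df$x)), y = sort(unique(df$y)), z = sort(unique(df$z)))
  n_expect <- prod(vapply(axes, length, integer(1)))
  if (nrow(df) != n_expect) {
    stop("coordinates do not form a complete structured lattice: ",
         nrow(df), " rows but ", n_expect, " lattice points.", call. = FALSE)
  }
  df <- dplyr::arrange(df, .data$z, .data$y, .data$x)
  flow_field(axes, velocity = df[, c("ux", "uy", "uz")])
}

read_velocity_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 9 || !grepl("^# vtk DataFile", lines[1])) {
    stop("not a legacy-VTK file (missing '# vtk DataFile' header): ", path, call. = FALSE)
  }
  if (toupper(trimws(lines[3])) != "ASCII") {
    stop("only ASCII legacy-VTK files are supported.", call. = FALSE)
  }
  if (!grepl("STRUCTURED_POINTS", lines[4])) {
    stop("only DATASET STRUCTURED_POINTS is supported (got: ", trimws(lines[4]), ").",
         call. = FALSE)
  }
  get_nums <- function(key) {
    ln <- grep(paste0("^\\s*", key, "\\b"), lines, value = TRUE)
    if (length(ln) != 1) stop("malformed VTK header: expected one ", key, " line.", call. = FALSE)
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][-1])
  }
  dims <- get_nums("DIMENSIONS")
  origin <- get_nums("ORIGIN")
  spacing <- get_nums("SPACING")
  if (length(dims) != 3 || any(dims < 1) || anyNA(dims)) {
    stop("malformed DIMENSIONS line.", call. = FALSE)
  }
  n <- prod(dims)
  vec_i <- grep("^\\s*VECTORS\\s+velocity\\b", lines)
  if (length(vec_i) != 1) {
    stop("expected exactly one 'VECTORS velocity' attribute.", call. = FALSE)
  }
  data_lines <- lines[(vec_i + 1):length(lines)]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(data_lines), "\\s+"))))
  if (length(vals) < 3 * n) {
    stop("VECTORS data truncated: expected ", 3 * n, " numbers, found ", length(vals), ".",
         call. = FALSE)
  }
  vals <- vals[seq_len(3 * n)]
  if (any(!is.finite(vals))) stop("VTK velocity data contain non-finite values.", call. = FALSE)
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  axes <- list(
    x = origin[1] + spacing[1] * (seq_len(dims[1]) - 1),
    y = origin[2] + spacing[2] * (seq_len(dims[2]) - 1),
    z = origin[3] + spacing[3] * (seq_len(dims[3]) - 1)
  )
  flow_field(axes, velocity = tibble::tibble(ux = m[, 1], uy = m[, 2], uz = m[, 3]))
}

# Documented CSV schema of a conductivity field: 3 coordinates, 6 unique
# tensor components, 8 diagnostics.
tensor_csv_cols <- function() {
  c("x", "y", "z",
    "sxx", "syy", "szz", "sxy", "sxz", "syz",
    "gamma_dot_max", "tau_max", "f_aligned", "lambda_d",
    "sigma_alpha", "sigma_beta", "eta_aniso", "degenerate")
}

#' Write a conductivity tensor field
#'
#' CSV uses the documented 17-column schema (coordinates, the six unique
#' symmetric tensor components, eight diagnostics). Legacy VTK writes a
#' 9-component `TENSORS conductivity double` attribute plus scalar
#' diagnostic fields (uniform grids only).
#'
#' @param cfield A [conductivity_field()].
#' @param path Output file path.
#' @param format `"vtk"` or `"csv"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_tensor_field <- function(cfield, path, format = guess_format(path)) {
  format <- match.arg(format, c("vtk", "csv"))
  if (format == "csv") {
    write_csv17(tibble::as_tibble(cfield)[, tensor_csv_cols()], path)
    return(invisible(path))
  }
  ax <- attr(cfield, "axes", exact = TRUE)
  if (is.null(ax)) stop("conductivity field carries no grid axes; write CSV instead.", call. = FALSE)
  sp <- axes_uniform_spacing(ax)
  n <- vapply(ax, length, integer(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "hemocond conductivity tensor field",
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    paste("DIMENSIONS", n[1], n[2], n[3]),
    paste("ORIGIN", fmt17(ax$x[1]), fmt17(ax$y[1]), fmt17(ax$z[1])),
    paste("SPACING", fmt17(sp[1]), fmt17(sp[2]), fmt17(sp[3])),
    paste("POINT_DATA", nrow(cfield)),
    "TENSORS conductivity double"
  ), con)
  # 9 components per point, three rows of three (symmetric by construction)
  writeLines(paste0(
    fmt17(cfield$sxx), " ", fmt17(cfield$sxy), " ", fmt17(cfield$sxz), "\n",
    fmt17(cfield$sxy), " ", fmt17(cfield$syy), " ", fmt17(cfield$syz), "\n",
    fmt17(cfield$sxz), " ", fmt17(cfield$syz), " ", fmt17(cfield$szz), "\n"
  ), con)
  for (sc in c("gamma_dot_max", "tau_max", "eta_aniso")) {
    writeLines(c(paste("SCALARS", sc, "double 1"), "LOOKUP_TABLE default",
                 fmt17(cfield[[sc]])), con)
  }
  invisible(path)
}

#' Read a conductivity tensor field from CSV
#'
#' Round-trip companion of [write_tensor_field()]'s CSV dialect.
#'
#' @param path Input CSV path.
#' @return A tibble with the 17 documented columns.
#' @export
read_tensor_field <- function(path) {
  df <- read_csv_base(path)
  if ("degenerate" %in% names(df)) df$degenerate <- as.character(df$degenerate)
  missing <- setdiff(tensor_csv_cols(), names(df))
  if (length(missing) > 0) {
    stop("tensor CSV is missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

guess_format <- function(path) {
  if (grepl("\\.vtk$", path, ignore.case = TRUE)) "vtk" else "csv"
}

# --- flat key-value run configuration ---------------------------------------

config_schema <- function() {
  c("lambda", "sigma_pl", "hematocrit", "a", "b", "mu", "k", "eta_pl",
    "rho_bl", "eta_bl_override",
    "model", "vv_fallback", "eps_tau", "eps_lamb", "eps_repeat",
    "generator", "diameter", "u_mean", "swirl_rate", "length", "n", "nz",
    "seed", "amplitude",
    "input", "input_format", "output", "output_format", "log_level")
}

config_error <- function(msg) {
  stop(structure(class = c("hemocond_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Read a flat key-value run configuration
#'
#' Grammar: one `key = value` pair per line; blank lines and lines starting
#' with `#` are ignored. Unknown keys are rejected (listed in the error).
#' Numeric-looking values are converted to numbers.
#'
#' @param path Path to the configuration file.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) config_error(paste0("no such config file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      config_error(paste0("malformed config line (expected 'key = value'): ", ln))
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!(key %in% config_schema())) {
      config_error(paste0("unknown config key: `", key, "` (known keys: ",
                          paste(config_schema(), collapse = ", "), ")"))
    }
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

# blood_params() from a config list (unknown keys already rejected upstream)
params_from_config <- function(cfg) {
  args <- cfg[intersect(names(cfg), names(formals(blood_params)))]
  do.call(blood_params, args)
}
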