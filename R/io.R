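# CSV dialect for band-intensity tables.
#
# Plain CSV with '#'-prefixed metadata header lines ("# key: value"), so
# files stay human-editable and spreadsheet-safe while carrying the unit
# tag (mandatory — units are never inferred), the DNA concentration for
# titrations, and for synthetic files the generating truth and seed.
#
# Columns by kind:
#   cleavage:   time, F
#   cruciform:  time, S, N, L      (raw intensities; renormalized on read)
#   titration:  Pt, fb

fmt_num <- function(x) sprintf("%.15g", x)

#' Write a band-intensity table
#'
#' Serializes a [progress_curve()], [cruciform_trajectory()] or
#' [binding_titration()] to the package's CSV dialect: '#'-commented
#' metadata header lines (kind, unit tag, and for synthetic objects the
#' generating truth and seed) followed by a plain CSV body. Numbers are
#' written with 15 significant digits so a write/read round trip preserves
#' values to near machine precision.
#'
#' @param x the object to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_intensity_table()]
#' @export
write_intensity_table <- function(x, path) {
  meta <- list()
  if (inherits(x, "progress_curve")) {
    kind <- "cleavage"
    meta$time_unit <- attr(x, "time_unit")
    body <- data.frame(time = fmt_num(x$time), F = fmt_num(x$F))
  } else if (inherits(x, "cruciform_trajectory")) {
    kind <- "cruciform"
    meta$time_unit <- attr(x, "time_unit")
    body <- data.frame(time = fmt_num(x$time), S = fmt_num(x$fS),
                       N = fmt_num(x$fN), L = fmt_num(x$fL))
  } else if (inherits(x, "binding_titration")) {
    kind <- "titration"
    meta$conc_unit <- "nM"
    meta$Dt <- fmt_num(attr(x, "Dt"))
    meta$stoichiometry <- attr(x, "stoichiometry")
    body <- data.frame(Pt = fmt_num(x$Pt), fb = fmt_num(x$fb))
  } else {
    stop_domain("'x' must be a progress_curve, cruciform_trajectory or binding_titration")
  }
  meta <- c(list(kind = kind), meta)
  if (!is.null(attr(x, "truth"))) {
    meta$truth <- jsonlite::toJSON(attr(x, "truth"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(attr(x, "seed"))) meta$seed <- format(attr(x, "seed"))
  if (!is.null(attr(x, "noise_sd"))) meta$noise_sd <- fmt_num(attr(x, "noise_sd"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), unlist(meta)), con)
  write.table(body, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_meta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  m <- regmatches(hdr, regexec("^#\\s*([^:]+):\\s*(.*)$", hdr))
  meta <- list()
  for (g in m) if (length(g) == 3) meta[[trimws(g[2])]] <- trimws(g[3])
  meta
}

#' Read a band-intensity table
#'
#' Parses a CSV in the dialect written by [write_intensity_table()] and
#' returns the validated domain object for the stated experiment kind.
#' Cruciform tables may contain raw (un-normalized) band intensities; they
#' are converted to fractions by per-row renormalization. All validation
#' failures are typed conditions (inheriting `resolvr_io_error`) and name
#' the offending column or row: missing columns, a missing mandatory unit
#' tag, non-finite cells, non-monotone schedules and negative intensities
#' are all rejected. Metadata (`truth`, `seed`) embedded by the synthetic
#' generators is restored onto the returned object.
#'
#' @param path input file path.
#' @param kind `"cleavage"`, `"cruciform"` or `"titration"`. Must match the
#'   file's `kind` header when present.
#' @return A [progress_curve()], [cruciform_trajectory()] or
#'   [binding_titration()].
#' @export
read_intensity_table <- function(path, kind = c("cleavage", "cruciform", "titration")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  meta <- read_meta(path)
  if (!is.null(meta$kind) && meta$kind != kind) {
    stop_io(sprintf("file declares kind '%s' but '%s' was requested",
                    meta$kind, kind), "resolvr_kind_error")
  }
  df <- tryCatch(
    read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop_io(sprintf("cannot parse CSV: %s", conditionMessage(e)))
  )
  need <- switch(kind,
                 cleavage = c("time", "F"),
                 cruciform = c("time", "S", "N", "L"),
                 titration = c("Pt", "fb"))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_io(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
            "resolvr_missing_column")
  }
  for (cl in need) {
    v <- df[[cl]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1]
      stop_io(sprintf("column '%s' has a non-finite value in row %d", cl,
                      if (is.na(bad)) 1L else bad),
              "resolvr_value_error")
    }
  }
  obj <- switch(kind,
    cleavage = {
      check_unit_meta(meta, "cleavage")
      validate_io_schedule(df$time, "time")
      progress_curve(df$time, df$F, time_unit = meta$time_unit)
    },
    cruciform = {
      check_unit_meta(meta, "cruciform")
      validate_io_schedule(df$time, "time")
      for (cl in c("S", "N", "L")) {
        if (any(df[[cl]] < 0)) {
          stop_io(sprintf("negative intensity in column '%s', row %d",
                          cl, which(df[[cl]] < 0)[1]), "resolvr_value_error")
        }
      }
      cruciform_trajectory(df$time, df$S, df$N, df$L,
                           time_unit = meta$time_unit, renormalize = TRUE)
    },
    titration = {
      if (is.null(meta$Dt)) {
        stop_io("titration file lacks the mandatory '# Dt:' header",
                "resolvr_unit_error")
      }
      validate_io_schedule(df$Pt, "Pt")
      stoich <- if (is.null(meta$stoichiometry)) "dimer" else meta$stoichiometry
      binding_titration(df$Pt, df$fb, Dt = as.numeric(meta$Dt),
                        stoichiometry = stoich)
    })
  if (!is.null(meta$truth)) {
    attr(obj, "truth") <- jsonlite::fromJSON(meta$truth)
  }
  if (!is.null(meta$seed)) attr(obj, "seed") <- as.numeric(meta$seed)
  if (!is.null(meta$noise_sd)) attr(obj, "noise_sd") <- as.numeric(meta$noise_sd)
  obj
}

check_unit_meta <- function(meta, kind) {
  if (is.null(meta$time_unit)) {
    stop_io(sprintf("%s file lacks the mandatory '# time_unit:' header", kind),
            "resolvr_unit_error")
  }
  if (!meta$time_unit %in% time_units) {
    stop_io(sprintf("unknown time unit '%s' (expected %s)", meta$time_unit,
                    paste(time_units, collapse = " or ")),
            "resolvr_unit_error")
  }
}

validate_io_schedule <- function(x, what) {
  if (any(x < 0)) {
    stop_io(sprintf("negative %s in row %d", what, which(x < 0)[1]),
            "resolvr_value_error")
  }
  if (length(x) > 1 && any(diff(x) <= 0)) {
    stop_io(sprintf("'%s' not strictly increasing at row %d", what,
                    which(diff(x) <= 0)[1] + 1L),
            "resolvr_schedule_error")
  }
  invisible(x)
}

#' Write a structured fit report
#'
#' Serializes a `resolvr_fit` (and optionally its bootstrap intervals) to a
#' JSON report containing everything needed to reproduce it: tool version,
#' an MD5 checksum of the input data, all parameter estimates with standard
#' errors, residual sum of squares, AICc, convergence flag, and any seed.
#'
#' @param fit a `resolvr_fit`.
#' @param path output path; `NULL` returns the report as a list.
#' @param boot optional `resolvr_bootstrap` for the same fit.
#' @return The report list, invisibly if written to `path`.
#' @export
write_fit_report <- function(fit, path = NULL, boot = NULL) {
  if (!inherits(fit, "resolvr_fit")) stop_domain("'fit' must be a resolvr_fit")
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_intensity_table(fit$data, tmp)
  checksum <- unname(tools::md5sum(tmp))
  report <- list(
    tool = "resolvr",
    version = as.character(utils::packageVersion("resolvr")),
    model = fit$model,
    parameters = as.list(fit$estimate),
    std_errors = as.list(fit$se),
    rss = fit$rss,
    n_obs = fit$n_obs,
    aicc = fit$aicc,
    converged = fit$converged,
    options = fit$options[!vapply(fit$options, is.null, logical(1))],
    input_md5 = checksum
  )
  if (!is.null(fit$rates)) {
    report$acceleration <- fit$rates$acceleration
  }
  if (!is.null(fit$half_saturation)) {
    report$half_saturation <- fit$half_saturation
  }
  if (!is.null(boot)) {
    if (!inherits(boot, "resolvr_bootstrap")) {
      stop_domain("'boot' must be a resolvr_bootstrap")
    }
    report$bootstrap <- list(
      n_boot = boot$n_boot, n_fail = boot$n_fail, seed = boot$seed,
      level = boot$level,
      ci = apply(boot$ci, 1, as.list, simplify = FALSE)
    )
  }
  if (is.null(path)) return(report)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}
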