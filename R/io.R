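# Session file formats and report rendering.
#
# Session CSV dialect (one row per support reading, header required, UTF-8,
# '.' decimal separator; units are embedded in the column names so a file
# in the wrong units cannot be read silently):
#   set_id, state{alpha|beta}, support_id{1|2|3}, x_cm, y_cm, reading_g
# The per-set rotation angles, the rotation centre and optional references
# travel in a geometry JSON sidecar.

SESSION_COLUMNS <- c("set_id", "state", "support_id", "x_cm", "y_cm", "reading_g")

#' Write a simulated session to the session CSV dialect
#'
#' @param session A [simulate_session()] result.
#' @param path Output CSV path.
#' @return Invisibly, the data.frame written.
#' @export
write_session_csv <- function(session, path) {
  stopifnot(inherits(session, "simulated_session"))
  rows <- lapply(session$pairs, function(p) {
    do.call(rbind, lapply(c("alpha", "beta"), function(st) {
      ss <- p[[st]]
      data.frame(set_id = p$set_id, state = st, support_id = 1:3,
                 x_cm = ss$points[, "x"], y_cm = ss$points[, "y"],
                 reading_g = ss$reading_g)
    }))
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Geometry sidecar for a session
#'
#' Collects the quantities that accompany a session CSV: the rotation
#' centre, the per-set recorded rotation angles, and optional calibrated
#' moment / declared total mass references.
#'
#' @param session A [simulate_session()] result.
#' @param rotation_center Rotation centre, cm.
#' @param calibrated_moment_kgcm Optional calibrated reference moment.
#' @param declared_total_kg Optional declared total supported mass.
#' @return A list in the geometry JSON layout.
#' @export
session_geometry <- function(session, rotation_center = c(0, 0),
                             calibrated_moment_kgcm = NULL,
                             declared_total_kg = NULL) {
  stopifnot(inherits(session, "simulated_session"))
  theta <- lapply(session$pairs, function(p) p$theta_deg)
  names(theta) <- vapply(session$pairs, function(p) p$set_id, character(1))
  g <- list(rotation_center = as.numeric(rotation_center), theta_deg = theta)
  if (!is.null(calibrated_moment_kgcm)) g$calibrated_moment_kgcm <- calibrated_moment_kgcm
  if (!is.null(declared_total_kg)) g$declared_total_kg <- declared_total_kg
  g
}

#' @rdname session_geometry
#' @param geometry A geometry list as returned by [session_geometry()].
#' @param path JSON file path.
#' @export
write_geometry_json <- function(geometry, path) {
  jsonlite::write_json(geometry, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(geometry)
}

#' @rdname session_geometry
#' @export
read_geometry_json <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(g$rotation_center) || is.null(g$theta_deg)) {
    stop_segmoment("geometry JSON must provide 'rotation_center' and 'theta_deg'",
                   "segmoment_parse_error")
  }
  g$rotation_center <- as.numeric(unlist(g$rotation_center))
  g$theta_deg <- lapply(g$theta_deg, as.numeric)
  g
}

parse_fail <- function(msg) stop_segmoment(msg, "segmoment_parse_error")

#' Read and validate a session CSV
#'
#' Reads the session dialect, checks the header, field types and state
#' labels, and verifies that every (set, state) has exactly the three
#' support rows. Errors name the offending row, set or state. Row order is
#' irrelevant.
#'
#' @param path CSV path.
#' @return A validated data.frame in the session dialect.
#' @export
read_session_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(SESSION_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    parse_fail(paste0("session CSV is missing column(s): ",
                      paste(missing_cols, collapse = ", ")))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) | df[[col]] == "")
    if (length(bad) > 0) {
      parse_fail(sprintf("non-numeric '%s' value at data row %d", col, bad[1L]))
    }
    v
  }
  df$support_id <- num("support_id")
  df$x_cm <- num("x_cm")
  df$y_cm <- num("y_cm")
  df$reading_g <- num("reading_g")
  bad_state <- which(!df$state %in% c("alpha", "beta"))
  if (length(bad_state) > 0) {
    parse_fail(sprintf("unknown state label '%s' at data row %d",
                       df$state[bad_state[1L]], bad_state[1L]))
  }
  bad_id <- which(!df$support_id %in% 1:3)
  if (length(bad_id) > 0) {
    parse_fail(sprintf("support_id must be 1, 2 or 3 (data row %d)", bad_id[1L]))
  }
  for (sid in unique(df$set_id)) {
    for (st in c("alpha", "beta")) {
      got <- sort(df$support_id[df$set_id == sid & df$state == st])
      if (!identical(got, c(1, 2, 3))) {
        parse_fail(sprintf("set '%s', state '%s': expected support rows {1,2,3}, got {%s}",
                           sid, st, paste(got, collapse = ",")))
      }
    }
  }
  df
}

#' Build measurement pairs from session data and geometry
#'
#' Groups a validated session data.frame by set, computes the alpha and
#' beta CoMs from the support readings, and attaches the per-set rotation
#' angle and the rotation centre from the geometry sidecar.
#'
#' @param session_df Data.frame from [read_session_csv()].
#' @param geometry Geometry list from [read_geometry_json()] or
#'   [session_geometry()].
#' @param mass_tol_kg Alpha/beta total-mass tolerance forwarded to
#'   [measurement_pair()].
#' @return A named list of [measurement_pair()] objects, one per set.
#' @export
session_pairs <- function(session_df, geometry,
                          mass_tol_kg = DEFAULT_MASS_TOL_KG) {
  sets <- unique(session_df$set_id)
  pairs <- lapply(sets, function(sid) {
    th <- geometry$theta_deg[[sid]]
    if (is.null(th)) {
      parse_fail(sprintf("geometry JSON has no rotation angle for set '%s'", sid))
    }
    states <- lapply(c(alpha = "alpha", beta = "beta"), function(st) {
      rows <- session_df[session_df$set_id == sid & session_df$state == st, ]
      rows <- rows[order(rows$support_id), ]
      compute_com(support_set(cbind(rows$x_cm, rows$y_cm), rows$reading_g),
                  label = st)
    })
    measurement_pair(states$alpha, states$beta, theta_deg = th,
                     rotation_center = geometry$rotation_center,
                     mass_tol_kg = mass_tol_kg)
  })
  names(pairs) <- sets
  pairs
}

format_percent <- function(x) sprintf("%.1f%%", x)

#' Render a session summary as report lines
#'
#' Human-readable report: n, mean, SD and, when a calibrated reference is
#' present, the RMS deviation; relative figures are rounded to one decimal
#' place (the JSON report keeps full precision). SD lines are omitted, not
#' zeroed, for single-estimate sessions.
#'
#' @param summary A [summarize_session()] result.
#' @return A character vector of report lines.
#' @export
render_report <- function(summary) {
  stopifnot(inherits(summary, "session_summary"))
  lines <- c(
    sprintf("n sets            : %d", summary$n),
    sprintf("mean moment       : %.1f kg.cm", summary$mean_kgcm)
  )
  if (!is.na(summary$sd_kgcm)) {
    lines <- c(lines,
      sprintf("SD                : %.3f kg.cm (%s of %s)",
              summary$sd_kgcm, format_percent(summary$relative_sd_pct),
              if (is.na(summary$calibrated_kgcm)) "mean" else "calibrated"))
  }
  if (!is.na(summary$rms_vs_calibrated_kgcm)) {
    lines <- c(lines,
      sprintf("calibrated moment : %.1f kg.cm", summary$calibrated_kgcm),
      sprintf("RMS vs calibrated : %.3f kg.cm (%s of calibrated)",
              summary$rms_vs_calibrated_kgcm,
              format_percent(summary$relative_rms_pct)))
  }
  lines
}

summary_as_list <- function(summary) {
  out <- unclass(summary)
  out$calibrated_kgcm <- if (is.na(out$calibrated_kgcm)) NULL else out$calibrated_kgcm
  out
}

#' Write a session report as JSON
#'
#' Full-precision machine-readable counterpart of [render_report()];
#' numbers are written at full (15 significant digit) precision, so
#' re-reading the JSON reproduces the in-memory summary to within the
#' decimal-text round trip.
#'
#' @param summary A [summarize_session()] result.
#' @param path Output JSON path.
#' @param estimates Optional list of [estimate_moment()] results to embed as
#'   a per-set table.
#' @return Invisibly, the list written.
#' @export
write_report_json <- function(summary, path, estimates = NULL) {
  out <- list(summary = summary_as_list(summary))
  if (!is.null(estimates)) {
    out$estimates <- lapply(estimates, function(e) {
      list(moment_kgcm = e$moment_kgcm, theta_deg = e$theta_deg,
           total_mass_kg = e$total_mass_kg,
           com1_alpha_cm = as.numeric(e$com1_alpha))
    })
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(out)
}
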