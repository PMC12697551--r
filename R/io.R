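#' Read a phenotype table
#'
#' Reads a delimited text file of one-row-per-subject-scan phenotype records
#' and validates it into the standard schema: `subject_id`, `age` (years),
#' `sex` (F/M), `batch` (site or scanner label), `value` (phenotype in native
#' units) and `group` (CN or CASE; defaults to CN when the column is
#' absent). Rows with missing age, sex or value are dropped with a message
#' reporting the count; an unknown sex or group level, or a missing mandated
#' column, is an error.
#'
#' @param path file path; delimiter is sniffed from the header line (`,` or
#'   tab) unless `delim` is given.
#' @param columns named list mapping schema names to file column names;
#'   defaults to identical names. `group` and `batch` may be absent from the
#'   file (defaults `CN` / `"batch1"`).
#' @param sexes,groups allowed level sets.
#' @param age_range declared study age range; ages outside are dropped along
#'   with missing-field rows.
#' @param delim optional explicit delimiter.
#' @return tibble of validated records with an attribute `n_dropped`.
#' @export
read_phenotype_table <- function(path,
                                 columns = list(),
                                 sexes = c("F", "M"),
                                 groups = c("CN", "CASE"),
                                 age_range = c(18, 100),
                                 delim = NULL) {
  defaults <- list(subject_id = "subject_id", age = "age", sex = "sex",
                   batch = "batch", value = "value", group = "group")
  columns <- utils::modifyList(defaults, columns)
  if (is.null(delim)) {
    header <- readLines(path, n = 1)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  mandatory <- c("subject_id", "age", "sex", "value")
  for (field in mandatory) {
    if (!columns[[field]] %in% names(raw)) {
      stop_refcal(
        paste0("Missing mandated column `", columns[[field]],
               "` (schema field `", field, "`)."),
        "refcal_schema_error"
      )
    }
  }
  out <- tibble(
    subject_id = raw[[columns$subject_id]],
    age = raw[[columns$age]],
    sex = raw[[columns$sex]],
    batch = if (columns$batch %in% names(raw)) raw[[columns$batch]] else "batch1",
    value = raw[[columns$value]],
    group = if (columns$group %in% names(raw)) raw[[columns$group]] else "CN"
  )
  # unparseable numerics are row-level errors; empty fields are dropped rows
  parse_num <- function(x, field) {
    trimmed <- trimws(x)
    val <- suppressWarnings(as.numeric(trimmed))
    bad <- which(!is.na(trimmed) & trimmed != "" & is.na(val))
    if (length(bad) > 0) {
      stop_refcal(
        paste0("Unparseable `", field, "` at data line ", bad[1],
               ": \"", x[bad[1]], "\"."),
        "refcal_parse_error"
      )
    }
    val[trimmed == ""] <- NA_real_
    val
  }
  out$age <- parse_num(out$age, "age")
  out$value <- parse_num(out$value, "value")
  out$sex[!is.na(out$sex) & trimws(out$sex) == ""] <- NA_character_
  out$group[is.na(out$group) | trimws(out$group) == ""] <- "CN"

  keep <- !is.na(out$age) & !is.na(out$sex) & !is.na(out$value) &
    out$age >= age_range[1] & out$age <= age_range[2] &
    is.finite(out$value)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    rlang::inform(paste0("Dropped ", n_dropped,
                         " row(s) with missing or out-of-range fields."))
  }
  out <- out[keep, , drop = FALSE]
  check_sex_levels(out$sex, sexes)
  bad_group <- setdiff(unique(out$group), groups)
  if (length(bad_group) > 0) {
    stop_refcal(paste0("Unknown group level(s): ",
                       paste(bad_group, collapse = ", "), "."),
                "refcal_schema_error")
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a reference interval as a gridded exchange file
#'
#' Serialises a reference interval by evaluating its bounds on an age grid
#' for each sex and writing a plain CSV (`sex, age, lower, upper`) preceded
#' by `#`-prefixed metadata lines (level, provenance, units, calibration
#' constants when present, creation info). The file round-trips exactly:
#' reading it back and evaluating at grid points reproduces the written
#' values bit for bit. This is the artifact that lets a calibrated chart be
#' shared without any subject-level data.
#'
#' @param interval a `ref_interval`.
#' @param path output file path.
#' @param age_grid ages at which to tabulate the bounds; default 101 equally
#'   spaced points over the interval's age range.
#' @param sexes sexes to tabulate; defaults to the interval's.
#' @param units free-text units annotation (e.g. `"mm"`).
#' @param timestamp include a creation-time metadata line.
#' @return (invisibly) the gridded tibble written.
#' @export
write_gridded_interval <- function(interval, path, age_grid = NULL,
                                   sexes = NULL, units = "unspecified",
                                   timestamp = TRUE) {
  sexes <- sexes %||% interval$sexes
  age_grid <- age_grid %||%
    seq(interval$age_range[1], interval$age_range[2], length.out = 101)
  if (is.unsorted(age_grid, strictly = TRUE)) {
    stop_refcal("`age_grid` must be strictly increasing.",
                "refcal_domain_error")
  }
  grid <- expand.grid(age = age_grid, sex = sexes,
                      stringsAsFactors = FALSE)[, c("sex", "age")]
  b <- interval_bounds(interval, grid$age, grid$sex)
  out <- tibble(sex = grid$sex, age = grid$age,
                lower = b$lower, upper = b$upper)

  meta <- c(
    paste0("# alpha=", sprintf("%.17g", interval$alpha)),
    paste0("# calibrated=", tolower(interval$calibrated)),
    paste0("# model=", interval$provenance),
    paste0("# units=", units),
    paste0("# age_range=", paste(sprintf("%.17g", interval$age_range),
                                 collapse = ","))
  )
  if (!is.null(interval$constants)) {
    cst <- interval$constants
    meta <- c(meta, paste0(
      "# constants=c_lower:", sprintf("%.17g", cst$c_lower),
      ";c_upper:", sprintf("%.17g", cst$c_upper),
      ";n_cal:", cst$n_cal, ";tail_level:", cst$tail_level,
      ";overflow_events:", cst$overflow_events
    ))
  }
  if (timestamp) {
    meta <- c(meta, paste0("# created=", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  }
  lines <- c(
    meta,
    "sex,age,lower,upper",
    sprintf("%s,%.17g,%.17g,%.17g", out$sex, out$age, out$lower,
            out$upper)
  )
  writeLines(lines, path)
  invisible(out)
}

#' Read a gridded reference-interval file
#'
#' @param path file written by [write_gridded_interval()].
#' @return an object of class `gridded_interval`: a tibble (`sex`, `age`,
#'   `lower`, `upper`) with attributes `alpha`, `calibrated`, `model`,
#'   `units` and (when present) the calibration constants.
#' @export
read_gridded_interval <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub("=.*$", "", kv)
    meta[[key]] <- sub("^[^=]*=", "", kv)
  }
  body <- lines[!grepl("^#", lines)]
  # base parser (strtod) is correctly rounded, so 17-digit decimals
  # round-trip the underlying doubles bit-exactly
  tbl <- as_tibble(utils::read.csv(
    text = paste(body, collapse = "\n"),
    colClasses = c(sex = "character")
  ))
  required <- c("sex", "age", "lower", "upper")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    stop_refcal(paste0("Gridded interval file lacks column(s): ",
                       paste(missing_cols, collapse = ", "), "."),
                "refcal_schema_error")
  }
  for (s in unique(tbl$sex)) {
    sub <- tbl[tbl$sex == s, ]
    if (is.unsorted(sub$age, strictly = TRUE)) {
      stop_refcal(paste0("Ages not strictly increasing for sex ", s, "."),
                  "refcal_schema_error")
    }
    if (any(sub$upper < sub$lower) && !identical(meta$calibrated, "true")) {
      stop_refcal(paste0("upper < lower at a grid point for sex ", s, "."),
                  "refcal_schema_error")
    }
  }
  structure(
    as_tibble(tbl),
    class = c("gridded_interval", class(as_tibble(tbl))),
    alpha = as.numeric(meta$alpha %||% NA),
    calibrated = identical(meta$calibrated, "true"),
    model = meta$model %||% "unknown",
    units = meta$units %||% "unspecified",
    constants_meta = meta$constants
  )
}

#' Rebuild a reference interval from a gridded file by interpolation
#'
#' Returns bound functions that are piecewise linear in age within each sex;
#' evaluation at grid points is exact. Evaluation outside
#' `[min(grid) - margin, max(grid) + margin]` raises an extrapolation error;
#' within the margin the boundary value is extended as a constant.
#'
#' @param gridded a `gridded_interval` from [read_gridded_interval()].
#' @param margin allowed extrapolation margin in years (default 0).
#' @return a `ref_interval`.
#' @export
interpolate_interval <- function(gridded, margin = 0) {
  stopifnot(inherits(gridded, "gridded_interval"))
  alpha <- attr(gridded, "alpha")
  sexes <- unique(gridded$sex)
  tabs <- split(as_tibble(gridded), gridded$sex)
  rng <- range(gridded$age)

  make_bound <- function(which) {
    force(which)
    function(age, sex) {
      k <- max(length(age), length(sex))
      age <- rep_len(age, k)
      sex <- rep_len(as.character(sex), k)
      out <- numeric(k)
      if (any(age < rng[1] - margin - 1e-12 | age > rng[2] + margin + 1e-12)) {
        bad <- which(age < rng[1] - margin - 1e-12 |
                     age > rng[2] + margin + 1e-12)[1]
        stop_refcal(
          paste0("Age ", age[bad], " outside the gridded range [",
                 rng[1], ", ", rng[2], "] + margin ", margin, "."),
          "refcal_extrapolation_error"
        )
      }
      for (s in unique(sex)) {
        tab <- tabs[[s]]
        if (is.null(tab)) {
          stop_refcal(paste0("Sex level ", s, " not present in the grid."),
                      "refcal_schema_error")
        }
        idx <- sex == s
        if (nrow(tab) == 1) {
          out[idx] <- tab[[which]]
        } else {
          xc <- pmin(pmax(age[idx], rng[1]), rng[2])
          yi <- approx(tab$age, tab[[which]], xout = xc,
                       method = "linear")$y
          # exact node hits reproduce the tabulated value bit for bit
          hit <- match(xc, tab$age)
          yi[!is.na(hit)] <- tab[[which]][hit[!is.na(hit)]]
          out[idx] <- yi
        }
      }
      out
    }
  }

  constants <- NULL
  cm <- attr(gridded, "constants_meta")
  if (!is.null(cm)) {
    parts <- strsplit(strsplit(cm, ";")[[1]], ":")
    vals <- setNames(vapply(parts, `[`, "", 2), vapply(parts, `[`, "", 1))
    constants <- tibble(
      c_lower = as.numeric(vals[["c_lower"]]),
      c_upper = as.numeric(vals[["c_upper"]]),
      n_cal = as.integer(vals[["n_cal"]]),
      alpha = alpha,
      tail_level = unname(vals[["tail_level"]]),
      overflow_events = as.integer(vals[["overflow_events"]])
    )
  }
  new_ref_interval(
    alpha,
    lower = make_bound("lower"), upper = make_bound("upper"),
    calibrated = attr(gridded, "calibrated"),
    provenance = paste0("interpolated(", attr(gridded, "model"), ")"),
    age_range = rng, sexes = sexes, constants = constants
  )
}
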