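# CSV interchange: header row, UTF-8, "." decimal separator, units in column
# names, numbers written with %.12g (lossless for the declared precisions:
# angles 1e-9 deg, volumes 1e-6 mm^3) so identical inputs yield byte-identical
# files.

fmt_num <- function(x) {
  out <- sprintf("%.12g", x)
  out[!is.finite(x)] <- "NA"
  out
}

write_csv_fixed <- function(df, path) {
  is_num <- vapply(df, is.numeric, TRUE)
  out <- df
  out[is_num] <- lapply(df[is_num], fmt_num)
  con <- file(path, open = "wb")       # binary: LF endings on all platforms
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con)
  if (nrow(out) > 0L) {
    writeLines(do.call(paste, c(unname(as.list(out)), sep = ",")), con)
  }
  invisible(path)
}

#' Write a trial to CSV
#'
#' Columns: `time_s, flexion_deg, adduction_deg, int_rot_deg` and, for
#' running trials, `grf_vertical_N`. Metadata (subject, kind, condition)
#' goes into `# key: value` comment lines before the header.
#'
#' @param tr An `hmp_trial`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(tr, path) {
  stopifnot(inherits(tr, "hmp_trial"))
  df <- data.frame(time_s = tr$time, flexion_deg = tr$flexion_deg,
                   adduction_deg = tr$adduction_deg,
                   int_rot_deg = tr$int_rot_deg)
  if (!is.null(tr$grf_vertical_N)) df$grf_vertical_N <- tr$grf_vertical_N
  con <- file(path, open = "wb")
  writeLines(c(sprintf("# subject_id: %s", tr$subject_id),
               sprintf("# movement_kind: %s", tr$movement_kind),
               sprintf("# condition: %s", tr$condition)), con)
  close(con)
  tmp <- tempfile()
  write_csv_fixed(df, tmp)
  file.append(path, tmp)
  unlink(tmp)
  invisible(path)
}

#' Read a trial from CSV
#'
#' Validates the schema (named error for a missing column) and the
#' uniform-time invariant (error reporting the maximum gap deviation).
#' Trailing blank lines are tolerated.
#'
#' @param path Path to a trial CSV written by [write_trial_csv()] (or any
#'   file with the same schema).
#' @return An `hmp_trial`.
#' @export
read_trial_csv <- function(path) {
  if (!file.exists(path)) stop("trial file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta <- list(subject_id = "unknown", movement_kind = "squat",
               condition = "unknown")
  hdr <- grep("^#", lines, value = TRUE)
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([a-z_]+):\\s*(.+)$", h))[[1]]
    if (length(m) == 3L && m[2] %in% names(meta)) meta[[m[2]]] <- trimws(m[3])
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  need <- c("time_s", "flexion_deg", "adduction_deg", "int_rot_deg")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("trial CSV ", basename(path), " missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dt <- diff(df$time_s)
  if (length(dt) > 0L) {
    gap <- max(abs(dt - dt[1]))
    if (gap > 1e-6) {
      stop(sprintf("non-uniform time in %s: max gap deviation %.3g s",
                   basename(path), gap), call. = FALSE)
    }
  }
  trial(df$time_s, df$flexion_deg, df$adduction_deg, df$int_rot_deg,
        grf_vertical_N = df[["grf_vertical_N"]],
        movement_kind = meta$movement_kind,
        subject_id = meta$subject_id, condition = meta$condition)
}

#' Write / read a cartilage volume table
#'
#' Schema: subject, condition, region, pre_mm3, post_mm3, mass_kg, height_m.
#'
#' @param cart Cartilage data frame.
#' @param path File path.
#' @return The path (write) or validated data frame (read).
#' @export
write_cartilage_csv <- function(cart, path) {
  keep <- c("subject", "condition", "region", "pre_mm3", "post_mm3",
            "mass_kg", "height_m")
  write_csv_fixed(cart[keep], path)
}

#' @rdname write_cartilage_csv
#' @export
read_cartilage_csv <- function(path) {
  if (!file.exists(path)) {
    stop("cartilage file not found: ", path, call. = FALSE)
  }
  cart <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cartilage(cart)
  cart
}

#' Write a synthetic cohort to a dataset directory
#'
#' Lays out one CSV per trial under `trials/`, the cartilage table, the
#' ground-truth table and a JSON manifest listing every file with subject,
#' kind and condition. Deterministic: the same cohort writes byte-identical
#' files.
#'
#' @param cohort An `hmp_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hmp_cohort"))
  dir.create(file.path(dir, "trials"), recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  counters <- new.env()
  for (tr in cohort$trials) {
    key <- paste(tr$subject_id, tr$movement_kind, tr$condition, sep = "_")
    k <- (if (is.null(counters[[key]])) 0L else counters[[key]]) + 1L
    counters[[key]] <- k
    fn <- sprintf("%s_%03d.csv", key, k)
    write_trial_csv(tr, file.path(dir, "trials", fn))
    entries[[length(entries) + 1L]] <- list(
      file = file.path("trials", fn), subject_id = tr$subject_id,
      movement_kind = tr$movement_kind, condition = tr$condition)
  }
  write_cartilage_csv(cohort$cartilage, file.path(dir, "cartilage.csv"))
  write_csv_fixed(cohort$truth_table, file.path(dir, "truth.csv"))
  manifest <- list(n_subjects = cohort$cfg$n_subjects,
                   shoes = cohort$cfg$shoes, seed = cohort$cfg$seed,
                   trials = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full analysis pipeline on a dataset directory
#'
#' Reads every trial and the cartilage table, computes per-subject baselines
#' from the half-squats, per-stride and per-condition deviations, subject
#' summaries, percent reductions, and the statistical battery. Trials whose
#' flexion never crosses the critical angle are excluded with a logged
#' reason, never dropped silently.
#'
#' @param data_dir Dataset directory (layout of [write_cohort()]); a
#'   `manifest.json` is used if present, otherwise `trials/*.csv` are
#'   scanned.
#' @param config An `analysis_config`.
#' @param out_dir Optional directory for output artifacts (baselines,
#'   deviations, summaries, reductions CSVs and `report.json`).
#' @return A list of class `pipeline_result`: `baselines`, `deviations`
#'   (data frame), `summaries`, `reductions`, `study`, `log` (data frame of
#'   per-trial dispositions).
#' @export
run_pipeline <- function(data_dir, config = analysis_config(),
                         out_dir = NULL) {
  trial_dir <- file.path(data_dir, "trials")
  files <- sort(list.files(trial_dir, pattern = "\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0L) {
    stop("no trial CSVs found under ", trial_dir, call. = FALSE)
  }
  cart_path <- file.path(data_dir, "cartilage.csv")
  if (!file.exists(cart_path)) {
    stop("cartilage.csv not found under ", data_dir, call. = FALSE)
  }
  trials <- lapply(files, read_trial_csv)
  cart <- read_cartilage_csv(cart_path)
  analyze_cohort(trials, cart, config, out_dir = out_dir)
}

#' Analyse in-memory trials and cartilage records
#'
#' The computational core of [run_pipeline()], usable directly on a cohort
#' from [generate_cohort()] without touching the filesystem.
#'
#' @param trials List of `hmp_trial` objects (squats and runs, any order).
#' @param cartilage Cartilage volume table.
#' @param config An `analysis_config`.
#' @param out_dir Optional artifact directory.
#' @return A `pipeline_result` (see [run_pipeline()]).
#' @export
analyze_cohort <- function(trials, cartilage, config = analysis_config(),
                           out_dir = NULL) {
  if (inherits(trials, "hmp_cohort")) {
    if (missing(cartilage) || is.null(cartilage)) {
      cartilage <- trials$cartilage
    }
    trials <- trials$trials
  }
  log_rows <- list()
  note <- function(tr, status, reason = "") {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      subject = tr$subject_id, kind = tr$movement_kind,
      condition = tr$condition, status = status, reason = reason,
      stringsAsFactors = FALSE)
  }

  subjects <- sort(unique(vapply(trials, function(t) t$subject_id, "")))
  baselines <- list()
  dev_rows <- list()
  summaries <- list()
  for (sid in subjects) {
    mine <- Filter(function(t) t$subject_id == sid, trials)
    squats <- Filter(function(t) t$movement_kind == "squat", mine)
    runs <- Filter(function(t) t$movement_kind == "run", mine)
    crossings <- list()
    n_excl <- 0L
    for (tr in squats) {
      cr <- tryCatch(critical_angles(tr, config), error = function(e) e)
      if (inherits(cr, "error")) {
        n_excl <- n_excl + 1L
        note(tr, "excluded", conditionMessage(cr))
      } else {
        crossings[[length(crossings) + 1L]] <- as.numeric(cr)
        note(tr, "used")
      }
    }
    bl <- compute_baseline(crossings, subject_id = sid, n_excluded = n_excl)
    baselines[[sid]] <- bl

    conds <- unique(vapply(runs, function(t) t$condition, ""))
    per_shoe <- list()
    for (cd in conds) {
      strides <- Filter(function(t) t$condition == cd, runs)
      devs <- list()
      for (tr in strides) {
        cr <- tryCatch(critical_angles(tr, config), error = function(e) e)
        if (inherits(cr, "error")) {
          note(tr, "excluded", conditionMessage(cr))
        } else {
          devs[[length(devs) + 1L]] <-
            compute_deviation(cr, bl, config$eq1_transverse_weight,
                              config$signed_deviation)
          note(tr, "used")
        }
      }
      if (length(devs) == 0L) next
      agg <- aggregate_condition(devs, subject_id = sid, condition = cd,
                                 transverse_weight =
                                   config$eq1_transverse_weight)
      per_shoe[[cd]] <- agg
      dev_rows[[length(dev_rows) + 1L]] <- data.frame(
        subject = sid, condition = cd,
        dev_front_deg = agg$dev_front_deg, dev_trans_deg = agg$dev_trans_deg,
        dev_total_deg = agg$dev_total_deg, n_strides = agg$n_strides,
        stringsAsFactors = FALSE)
    }
    summaries[[sid]] <- summarize_subject(per_shoe,
                                          tie_order = config$tie_shoe_order)
  }

  reductions <- reduction_table(cartilage)
  study <- run_study_analysis(summaries, reductions, config)
  res <- structure(list(
    baselines = baselines,
    deviations = do.call(rbind, dev_rows),
    summaries = summaries,
    reductions = reductions,
    study = study,
    log = do.call(rbind, log_rows)), class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_artifacts(res, out_dir)
  res
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bl <- do.call(rbind, lapply(res$baselines, function(b) data.frame(
    subject = b$subject_id, frontal_deg = b$frontal_deg,
    transverse_deg = b$transverse_deg, n_squats_used = b$n_squats_used,
    n_excluded = b$n_excluded, stringsAsFactors = FALSE)))
  write_csv_fixed(bl, file.path(out_dir, "baselines.csv"))
  write_csv_fixed(res$deviations, file.path(out_dir, "deviations.csv"))
  summ <- do.call(rbind, lapply(res$summaries, function(s) data.frame(
    subject = s$subject_id, overall_deg = s$overall_deg,
    min_shoe = s$min_shoe, max_shoe = s$max_shoe, stringsAsFactors = FALSE)))
  write_csv_fixed(summ, file.path(out_dir, "summaries.csv"))
  write_csv_fixed(res$reductions, file.path(out_dir, "reductions.csv"))
  write_csv_fixed(res$log, file.path(out_dir, "log.csv"))
  report <- list(groups = res$study$groups,
                 alpha = res$study$alpha,
                 group_tests = res$study$group_tests,
                 footwear_tests = res$study$footwear_tests,
                 regressions = res$study$regressions)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 12,
                       dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subjects | %d trials used, %d excluded\n",
              length(x$baselines), sum(x$log$status == "used"),
              sum(x$log$status == "excluded")))
  print(x$study)
  invisible(x)
}
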