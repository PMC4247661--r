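#' Pipeline configuration
#'
#' Bundles every tunable of the processing pipeline: non-wear rule
#' parameters per rule/axis, intensity cut-points per axis, and the
#' valid-day wear threshold. `read_config()` loads overrides from a YAML
#' file with (optional) top-level blocks `valid_min`, `cutpoints` (keys
#' `vertical`/`vm`, each with `sedentary_upper`/`mvpa_lower`) and `nonwear`
#' (keys `troiano`/`choi`, each with `vertical`/`vm` parameter lists passed
#' to [nonwear_params()]).
#'
#' @param valid_min Valid-day wear threshold in minutes (default 600).
#' @param cutpoints Named list `vertical`/`vm` of [intensity_cutpoints()].
#' @param nonwear Named list `troiano`/`choi`, each `vertical`/`vm`, of
#'   [nonwear_params()].
#' @return A list of class `"grid_config"`.
#' @export
grid_config <- function(valid_min = 600,
                        cutpoints = list(vertical = intensity_cutpoints("vertical"),
                                         vm = intensity_cutpoints("vm")),
                        nonwear = list(
                          troiano = list(vertical = troiano_params("vertical"),
                                         vm = troiano_params("vm")),
                          choi = list(vertical = choi_params("vertical"),
                                      vm = choi_params("vm")))) {
  structure(list(valid_min = valid_min, cutpoints = cutpoints,
                 nonwear = nonwear), class = "grid_config")
}

#' @rdname grid_config
#' @param path Path to a YAML configuration file.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- grid_config()
  if (!is.null(y$valid_min)) cfg$valid_min <- y$valid_min
  for (ax in c("vertical", "vm")) {
    o <- y$cutpoints[[ax]]
    if (!is.null(o))
      cfg$cutpoints[[ax]] <- do.call(intensity_cutpoints, c(list(axis = ax), o))
    for (rule in c("troiano", "choi")) {
      p <- y$nonwear[[rule]][[ax]]
      if (!is.null(p))
        cfg$nonwear[[rule]][[ax]] <-
          do.call(nonwear_params, c(list(rule = rule, axis = ax), p))
    }
  }
  cfg
}

wear_methods <- function() c("detailed_log", "troiano", "choi",
                             "limited_log_troiano", "limited_log_choi")

# masks for all five wear methods on one subject, for one axis
subject_masks <- function(series, log_imputed, config, axis) {
  troiano <- troiano_nonwear(axis_counts(series, axis),
                             config$nonwear$troiano[[axis]])
  choi <- choi_nonwear(axis_counts(series, axis),
                       config$nonwear$choi[[axis]])
  list(
    detailed_log = detailed_log_mask(log_imputed, series),
    troiano = troiano,
    choi = choi,
    limited_log_troiano = limited_log_restrict(troiano, log_imputed, series),
    limited_log_choi = limited_log_restrict(choi, log_imputed, series)
  )
}

#' Run the full method-comparison grid over a cohort
#'
#' The pipeline driver: for every subject, derives the five wear masks
#' (detailed-log; Troiano and Choi algorithms alone; the two limited-log
#' hybrids that restrict algorithm output to the dates recorded on the log)
#' on each of the two count signals (vertical axis, vector magnitude),
#' summarizes days and subjects under the matching cut-points, and
#' aggregates cohort summaries plus vertical-vs-VM paired comparisons
#' (Wilcoxon signed-rank per metric; Bland-Altman for MVPA) within each
#' wear method. Deterministic given inputs and configuration. Subjects
#' failing hard validation (e.g. a log with no usable dates, which makes
#' the limited-log methods impossible) are excluded with a logged reason.
#'
#' @param cohort A list of subjects, each a list with elements `series`
#'   (an [epoch_series()]) and `log` (a [monitor_log()]), as produced by
#'   [simulate_cohort()].
#' @param eligible_n Eligible cohort size for percentage denominators
#'   (default `length(cohort)`).
#' @param config A [grid_config()].
#' @return An object of class `"wear_grid"`: list with `subject_metrics`
#'   (long data.frame: subject, method, axis, subject-level summary),
#'   `summaries` (cohort_summary per `method.axis`), `paired` (per method:
#'   `wilcoxon` per metric and `bland_altman` for MVPA), `exclusions`
#'   (data.frame subject/reason), `eligible_n`, `config`.
#' @export
run_grid <- function(cohort, eligible_n = length(cohort),
                     config = grid_config()) {
  stopifnot(length(cohort) >= 1L)
  exclusions <- data.frame(subject_id = character(), reason = character(),
                           stringsAsFactors = FALSE)
  rows <- list()
  for (subj in cohort) {
    series <- subj$series
    log_imp <- impute_meridiem(subj$log)$log
    res <- tryCatch({
      per_axis <- lapply(c(vertical = "vertical", vm = "vm"), function(ax) {
        masks <- subject_masks(series, log_imp, config, ax)
        lapply(masks, function(m) {
          days <- summarize_days(series, m, config$cutpoints[[ax]],
                                 valid_min = config$valid_min)
          summarize_subject(days, series$subject_id)
        })
      })
      for (ax in names(per_axis))
        for (meth in names(per_axis[[ax]])) {
          row <- per_axis[[ax]][[meth]]
          row$method <- meth
          row$axis <- ax
          rows[[length(rows) + 1L]] <- row
        }
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(res))
      exclusions <- rbind(exclusions,
                          data.frame(subject_id = series$subject_id,
                                     reason = res, stringsAsFactors = FALSE))
  }
  if (length(rows) == 0L) stop("run_grid: no subject passed validation")
  subject_metrics <- do.call(rbind, rows)

  summaries <- list()
  for (meth in wear_methods())
    for (ax in c("vertical", "vm")) {
      sub <- subject_metrics[subject_metrics$method == meth &
                               subject_metrics$axis == ax, , drop = FALSE]
      summaries[[paste(meth, ax, sep = ".")]] <-
        summarize_cohort(sub, eligible_n = eligible_n)
    }

  paired <- list()
  for (meth in wear_methods()) {
    v <- subject_metrics[subject_metrics$method == meth &
                           subject_metrics$axis == "vertical", , drop = FALSE]
    w <- subject_metrics[subject_metrics$method == meth &
                           subject_metrics$axis == "vm", , drop = FALSE]
    m <- merge(v, w, by = "subject_id", suffixes = c(".v", ".vm"))
    keep <- m$has_1_valid.v & m$has_1_valid.vm
    m <- m[keep, , drop = FALSE]
    if (nrow(m) < 2L) next
    tests <- lapply(c(wear_min = "wear_min", sedentary_min = "sedentary_min",
                      light_min = "light_min", mvpa_min = "mvpa_min"),
                    function(met) wilcoxon_signed_rank(m[[paste0(met, ".v")]],
                                                       m[[paste0(met, ".vm")]]))
    paired[[meth]] <- list(
      n = nrow(m),
      wilcoxon = tests,
      bland_altman = bland_altman(m$mvpa_min.v, m$mvpa_min.vm)
    )
  }

  structure(list(subject_metrics = subject_metrics, summaries = summaries,
                 paired = paired, exclusions = exclusions,
                 eligible_n = eligible_n, config = config),
            class = "wear_grid")
}

#' @export
print.wear_grid <- function(x, ...) {
  cat(sprintf("<wear_grid> %d eligible subjects, %d excluded\n",
              x$eligible_n, nrow(x$exclusions)))
  cat("\nSample size and wear time by method and axis:\n")
  for (nm in names(x$summaries)) {
    s <- x$summaries[[nm]]
    cat(sprintf("  %-28s >=1 valid: %5.1f%%  >=4 valid: %5.1f%%  >7 valid: %5.1f%%  wear %7.1f min\n",
                nm, s$pct_ge1_valid, s$pct_ge4_valid, s$pct_gt7_valid,
                s$metrics$median[s$metrics$metric == "wear_min"]))
  }
  cat("\nVertical vs VM (paired, within method):\n")
  for (nm in names(x$paired)) {
    p <- x$paired[[nm]]
    cat(sprintf("  %-22s MVPA bias (VM-V) %6.2f min, LoA (%.2f, %.2f); Wilcoxon p = %.3g\n",
                nm, p$bland_altman$bias, p$bland_altman$loa_lower,
                p$bland_altman$loa_upper, p$wilcoxon$mvpa_min$p_value))
  }
  invisible(x)
}

#' @export
summary.wear_grid <- function(object, ...) {
  s <- lapply(object$summaries, function(cs) {
    m <- cs$metrics
    data.frame(pct_ge1_valid = cs$pct_ge1_valid,
               pct_ge4_valid = cs$pct_ge4_valid,
               pct_gt7_valid = cs$pct_gt7_valid,
               valid_days_median = unname(cs$valid_days["median"]),
               wear_median = m$median[m$metric == "wear_min"],
               sedentary_median = m$median[m$metric == "sedentary_min"],
               light_median = m$median[m$metric == "light_min"],
               mvpa_median = m$median[m$metric == "mvpa_min"])
  })
  out <- do.call(rbind, s)
  parts <- strsplit(names(object$summaries), ".", fixed = TRUE)
  out <- cbind(data.frame(method = vapply(parts, `[`, "", 1),
                          axis = vapply(parts, `[`, "", 2)), out)
  rownames(out) <- NULL
  out
}
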