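#' Validate plate records
#'
#' A plate-record table holds one transformant line per row: identity
#' columns (`line_id`, `construct`, `strain`, `selection`, `experiment_id`),
#' per-round viability calls `viable_r1 ... viable_rR` (logical; a line that
#' has died must stay dead — viability is monotone non-increasing), and a
#' `gfp` call (logical, `NA` = not assessed; only final-round survivors are
#' assessed).
#'
#' @param records Data frame of plate records.
#' @return The validated data frame (invisibly usable); errors name the
#'   first offending `line_id`.
#' @export
validate_plate_records <- function(records) {
  needed <- c("line_id", "construct", "strain", "experiment_id", "gfp")
  missing <- setdiff(needed, colnames(records))
  if (length(missing) > 0) {
    stop("plate records missing column(s): ", paste(missing, collapse = ", "))
  }
  vcols <- viability_columns(records)
  if (length(vcols) == 0) stop("plate records have no viable_r* columns")
  v <- as.matrix(records[, vcols, drop = FALSE])
  if (ncol(v) > 1) {
    for (r in 2:ncol(v)) {
      bad <- which(v[, r] & !v[, r - 1])
      if (length(bad) > 0) {
        stop("non-monotone viability (line revives at round ", r, "): line_id ",
             records$line_id[bad[1]])
      }
    }
  }
  records
}

viability_columns <- function(records) {
  vcols <- grep("^viable_r[0-9]+$", colnames(records), value = TRUE)
  vcols[order(as.integer(sub("^viable_r", "", vcols)))]
}

#' Transformation efficiency (colonies per microgram) with SEM
#'
#' Each record is one selection plate: `colonies` counted for `dna_ug`
#' micrograms of transforming DNA. Technical replicates within an
#' experiment are averaged first; the mean and standard error are then
#' taken over independent experiments (`sem = sd / sqrt(n_experiments)`).
#'
#' @param counts Data frame with columns `colonies`, `dna_ug`,
#'   `experiment_id` (plus anything else, ignored). Group by construct and
#'   strain before calling, or use [screen_summary()].
#' @return List `mean`, `sem`, `n_experiments`, `sem_defined` (`FALSE` when
#'   only one experiment is available; `sem` is then reported as 0).
#' @examples
#' transformation_efficiency(data.frame(colonies = c(100, 120),
#'                                      dna_ug = 1, experiment_id = 1:2))
#' @export
transformation_efficiency <- function(counts) {
  stopifnot(all(c("colonies", "dna_ug", "experiment_id") %in% colnames(counts)))
  if (nrow(counts) == 0) stop("no transformation counts supplied")
  if (any(counts$dna_ug <= 0)) stop("dna_ug must be > 0")
  rate <- counts$colonies / counts$dna_ug
  per_exp <- tapply(rate, counts$experiment_id, mean)
  n <- length(per_exp)
  m <- mean(per_exp)
  sem_defined <- n > 1
  list(mean = m,
       sem = if (sem_defined) stats::sd(per_exp) / sqrt(n) else 0,
       n_experiments = n,
       sem_defined = sem_defined)
}

#' Fraction of lines still viable at each subculture round
#'
#' The denominator is always the initially picked lines; the curve is
#' therefore monotone non-increasing (enforced on input via
#' [validate_plate_records()]).
#'
#' @param records Plate-record data frame (one selection regime).
#' @return Data frame `round`, `n_viable`, `pct_viable`.
#' @export
stability_curve <- function(records) {
  records <- validate_plate_records(records)
  vcols <- viability_columns(records)
  n0 <- nrow(records)
  if (n0 == 0) stop("no plate records supplied")
  data.frame(
    round = seq_along(vcols),
    n_viable = vapply(vcols, function(cl) sum(records[[cl]]), integer(1)),
    pct_viable = vapply(vcols, function(cl) 100 * mean(records[[cl]]), numeric(1)),
    row.names = NULL
  )
}

#' GFP-positive percentage among final-round survivors
#'
#' The denominator is the lines still viable at the last recorded round
#' (the antibiotic-resistant, "stable" transformants), not the initially
#' picked lines. Viable lines whose GFP status was not assessed (`NA`) are
#' excluded and counted.
#'
#' @param records Plate-record data frame.
#' @return List `pct_gfp_positive` (`NA` with `computable = FALSE` when no
#'   viable line was assessed), `n_viable`, `n_assessed`, `n_positive`,
#'   `n_unassessed`, `computable`.
#' @export
gfp_fraction <- function(records) {
  records <- validate_plate_records(records)
  vcols <- viability_columns(records)
  final <- records[[vcols[length(vcols)]]]
  gfp <- records$gfp[final]
  n_viable <- sum(final)
  n_assessed <- sum(!is.na(gfp))
  if (n_assessed == 0) {
    return(list(pct_gfp_positive = NA_real_, n_viable = n_viable,
                n_assessed = 0L, n_positive = 0L,
                n_unassessed = n_viable, computable = FALSE))
  }
  list(pct_gfp_positive = 100 * sum(gfp, na.rm = TRUE) / n_assessed,
       n_viable = n_viable, n_assessed = n_assessed,
       n_positive = sum(gfp, na.rm = TRUE),
       n_unassessed = n_viable - n_assessed, computable = TRUE)
}

#' Per construct-by-strain screen summary
#'
#' Combines the three quantitative outputs of the plate screen:
#' transformation efficiency (mean colonies/ug with SEM over experiments),
#' final-round viability percentage and GFP-positive percentage among
#' viable lines.
#'
#' @param records Plate-record data frame (all constructs/strains).
#' @param counts Colony-count data frame with `construct`, `strain`,
#'   `experiment_id`, `colonies`, `dna_ug`.
#' @return A `ScreenSummary` data frame, one row per construct x strain.
#' @export
screen_summary <- function(records, counts) {
  records <- validate_plate_records(records)
  groups <- unique(records[, c("construct", "strain")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    cs <- groups$construct[i]
    st <- groups$strain[i]
    rec <- records[records$construct == cs & records$strain == st, ]
    cnt <- counts[counts$construct == cs & counts$strain == st, ]
    curve <- stability_curve(rec)
    gfp <- gfp_fraction(rec)
    eff <- if (nrow(cnt) > 0) transformation_efficiency(cnt) else
      list(mean = NA_real_, sem = NA_real_, n_experiments = 0L)
    data.frame(
      construct = cs, strain = st,
      efficiency_mean = eff$mean, efficiency_sem = eff$sem,
      n_experiments = eff$n_experiments,
      pct_viable_final = curve$pct_viable[nrow(curve)],
      pct_gfp_positive = gfp$pct_gfp_positive,
      n_lines = nrow(rec),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ScreenSummary", "data.frame")
  out
}

#' Compare constructs to a baseline with two-tailed Mann-Whitney U tests
#'
#' One test per non-baseline construct, on per-experiment values (e.g.
#' per-experiment transformation efficiencies or viability percentages).
#' Raw p-values are reported by default, matching screens that report
#' unadjusted significance; Bonferroni or Benjamini-Hochberg adjustment is
#' available via `adjust`.
#'
#' @param values Data frame `construct`, `experiment_id`, `value`.
#' @param baseline Name of the baseline construct (must be present).
#' @param alpha Significance level (strict `p < alpha`), default 0.05.
#' @param adjust `"none"` (default), `"bonferroni"` or `"BH"`.
#' @param mode Passed to [mann_whitney_u()].
#' @return Data frame `construct`, `baseline`, `U`, `p_two_tailed`,
#'   `p_adjusted`, `method`, `significant`, `tested` (`FALSE` when a group
#'   has fewer than 2 experiments; such groups are flagged, not tested).
#' @export
compare_constructs <- function(values, baseline, alpha = 0.05,
                               adjust = c("none", "bonferroni", "BH"),
                               mode = "auto") {
  adjust <- match.arg(adjust)
  stopifnot(all(c("construct", "experiment_id", "value") %in% colnames(values)))
  if (!baseline %in% values$construct) stop("baseline construct not present: ", baseline)
  base_vals <- values$value[values$construct == baseline]
  others <- unique(values$construct)
  rows <- lapply(others, function(cs) {
    v <- values$value[values$construct == cs]
    if (cs == baseline) {
      return(data.frame(construct = cs, baseline = baseline,
                        U = length(v)^2 / 2, p_two_tailed = 1,
                        method = "self", tested = TRUE,
                        stringsAsFactors = FALSE))
    }
    if (length(v) < 2 || length(base_vals) < 2) {
      return(data.frame(construct = cs, baseline = baseline,
                        U = NA_real_, p_two_tailed = NA_real_,
                        method = "skipped", tested = FALSE,
                        stringsAsFactors = FALSE))
    }
    t <- mann_whitney_u(v, base_vals, mode = mode, alpha = alpha)
    data.frame(construct = cs, baseline = baseline,
               U = t$U, p_two_tailed = t$p_two_tailed,
               method = t$method, tested = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- out$p_two_tailed
  idx <- out$tested & out$construct != baseline
  if (adjust != "none" && any(idx)) {
    out$p_adjusted[idx] <- stats::p.adjust(out$p_two_tailed[idx], method = adjust)
  }
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  rownames(out) <- NULL
  out
}

#' Bubble-plot summary table
#'
#' One row per construct x strain with the three axes of the combined
#' visual summary: final-round viability (x), GFP-positive percentage among
#' viable lines (y), and transformation efficiency (bubble size).
#'
#' @param summaries A `ScreenSummary` data frame.
#' @return Data frame `construct`, `strain`, `pct_viable_final`,
#'   `pct_gfp_positive`, `efficiency_mean`.
#' @export
bubble_summary <- function(summaries) {
  cols <- c("construct", "strain", "pct_viable_final", "pct_gfp_positive",
            "efficiency_mean")
  if (nrow(summaries) == 0) {
    out <- summaries[, intersect(cols, colnames(summaries)), drop = FALSE]
    return(as.data.frame(out))
  }
  out <- as.data.frame(summaries)[, cols]
  rownames(out) <- NULL
  out
}
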