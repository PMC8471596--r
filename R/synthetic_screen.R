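#' Configuration for the stochastic plate-screen generator
#'
#' Models the screening workflow: per technical replicate, colony counts on
#' the selection plate are Poisson with mean `efficiency_mean * dna_ug`;
#' each picked line survives each subculture round independently with the
#' round's survival probability conditional on surviving the previous round
#' (so viability is monotone by construction); GFP is a Bernoulli call made
#' only on final-round survivors.
#'
#' @param constructs List of per-construct entries, each a list with
#'   `construct`, `strain`, `selection`, `efficiency_mean` (colonies/ug),
#'   `survival_probs` (vector, one probability per subculture round) and
#'   `gfp_prob` (conditional on final-round viability).
#' @param n_experiments Independent experiments (default 3).
#' @param n_lines Lines picked per experiment and construct (default 96,
#'   one microtitre plate).
#' @param n_tech_reps Technical replicate selection plates per experiment
#'   (default 6).
#' @param dna_ug Micrograms of plasmid per transformation (default 1).
#' @return A `ScreenGenConfig` list.
#' @export
screen_config <- function(constructs, n_experiments = 3, n_lines = 96,
                          n_tech_reps = 6, dna_ug = 1) {
  stopifnot(length(constructs) >= 1, n_experiments >= 1, n_lines >= 1,
            n_tech_reps >= 1, dna_ug > 0)
  for (cc in constructs) {
    stopifnot(!is.null(cc$construct), !is.null(cc$strain),
              is.numeric(cc$efficiency_mean), cc$efficiency_mean >= 0,
              all(cc$survival_probs >= 0 & cc$survival_probs <= 1),
              cc$gfp_prob >= 0, cc$gfp_prob <= 1)
  }
  rounds <- vapply(constructs, function(cc) length(cc$survival_probs), integer(1))
  if (length(unique(rounds)) != 1) {
    stop("all constructs in one config must share the number of rounds")
  }
  structure(list(constructs = constructs, n_experiments = n_experiments,
                 n_lines = n_lines, n_tech_reps = n_tech_reps,
                 dna_ug = dna_ug, n_rounds = rounds[1]),
            class = "ScreenGenConfig")
}

construct_entry <- function(construct, strain, selection, efficiency_mean,
                            survival_probs, gfp_prob) {
  list(construct = construct, strain = strain, selection = selection,
       efficiency_mean = efficiency_mean, survival_probs = survival_probs,
       gfp_prob = gfp_prob)
}

# split a marginal final-round viability into equal per-round survival
# probabilities (geometric split)
split_survival <- function(marginal, rounds = 3) {
  rep(marginal^(1 / rounds), rounds)
}

#' Packaged screen parameters for the terminator comparison
#'
#' Per-construct generator parameters for the cw15 zeocin screen,
#' transcribed from the published summary values: baseline RBCS2-terminator
#' efficiency 2.47e3 colonies/ug with 74% round-3 viability and 23%
#' GFP-positive survivors; CA1 5.50e3 colonies/ug, 13% viability reduction
#' and 81% GFP-positive; PSAD 83% GFP-positive; no-3'UTR control 1.63e3
#' colonies/ug and 25% GFP-positive with under-50% viability. Quantities
#' published only as figures or ranges (per-round curves, the remaining
#' efficiencies, short-terminator GFP rates of 15-35%, viability reductions
#' of 20-32%) are fixed once at values inside the stated ranges. Marginal
#' round-3 viabilities are split into equal per-round survival
#' probabilities.
#'
#' @param constructs Optional character vector to subset (e.g. `"RBCS2"`).
#' @param n_experiments,n_lines,n_tech_reps,dna_ug Passed to
#'   [screen_config()].
#' @return A `ScreenGenConfig`.
#' @export
published_screen_preset <- function(constructs = NULL, n_experiments = 3,
                                n_lines = 96, n_tech_reps = 6, dna_ug = 1) {
  tab <- list(
    construct_entry("noUTR", "cw15", "zeocin", 1630, split_survival(0.45), 0.25),
    construct_entry("RPL31", "cw15", "zeocin", 2000, split_survival(0.72), 0.20),
    construct_entry("RPS29", "cw15", "zeocin", 2200, split_survival(0.70), 0.32),
    construct_entry("RPL11", "cw15", "zeocin", 2100, split_survival(0.71), 0.25),
    construct_entry("RBCS2", "cw15", "zeocin", 2470, split_survival(0.74), 0.23),
    construct_entry("PSAD",  "cw15", "zeocin", 3300, split_survival(0.78), 0.83),
    construct_entry("THI4",  "cw15", "zeocin", 3000, split_survival(0.75), 0.65),
    construct_entry("METE",  "cw15", "zeocin", 3500, split_survival(0.70), 0.65),
    construct_entry("CA1",   "cw15", "zeocin", 5500, split_survival(0.87), 0.81),
    construct_entry("NIT1",  "cw15", "zeocin", 3800, split_survival(0.76), 0.68)
  )
  if (!is.null(constructs)) {
    keep <- vapply(tab, function(cc) cc$construct %in% constructs, logical(1))
    if (!any(keep)) stop("no matching construct in the preset")
    tab <- tab[keep]
  }
  screen_config(tab, n_experiments = n_experiments, n_lines = n_lines,
                n_tech_reps = n_tech_reps, dna_ug = dna_ug)
}

#' Packaged parameters for the deferred-selection workflow comparison
#'
#' Five subculture rounds: three non-selective rounds over which nearly all
#' lines persist (95/96 of initially picked lines), followed by two rounds
#' under zeocin that bring the overall marginal viability down to 49% of
#' the initially picked lines.
#'
#' @param n_experiments,n_lines Passed to [screen_config()].
#' @return A `ScreenGenConfig` with one construct (`RBCS2`, regime
#'   `deferred`).
#' @export
deferred_selection_preset <- function(n_experiments = 3, n_lines = 96) {
  p_ns <- (95 / 96)^(1 / 3)
  p_sel <- sqrt(0.49 / (95 / 96))
  screen_config(
    list(construct_entry("RBCS2", "cw15", "deferred", 2470,
                         c(rep(p_ns, 3), rep(p_sel, 2)), 0.23)),
    n_experiments = n_experiments, n_lines = n_lines)
}

#' Generate stochastic plate-screen data with known truth
#'
#' @param cfg A `ScreenGenConfig` (e.g. [published_screen_preset()]).
#' @param seed Integer RNG seed; fixed seed + config give identical output.
#' @return List `plates` (plate-record data frame: `line_id`, `construct`,
#'   `strain`, `selection`, `experiment_id`, `viable_r1..rR`, `gfp`),
#'   `colonies` (colony-count data frame: `construct`, `strain`,
#'   `experiment_id`, `tech_rep`, `colonies`, `dna_ug`) and `truth` (the
#'   generating parameters, one row per construct, plus the seed).
#' @export
gen_screen <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "ScreenGenConfig"))
  set.seed(seed)
  plates <- list()
  colonies <- list()
  for (cc in cfg$constructs) {
    R <- length(cc$survival_probs)
    for (e in seq_len(cfg$n_experiments)) {
      colonies[[length(colonies) + 1]] <- data.frame(
        construct = cc$construct, strain = cc$strain,
        experiment_id = e, tech_rep = seq_len(cfg$n_tech_reps),
        colonies = stats::rpois(cfg$n_tech_reps,
                                cc$efficiency_mean * cfg$dna_ug),
        dna_ug = cfg$dna_ug, stringsAsFactors = FALSE)

      alive <- matrix(FALSE, nrow = cfg$n_lines, ncol = R)
      prev <- rep(TRUE, cfg$n_lines)
      for (r in seq_len(R)) {
        surv <- stats::runif(cfg$n_lines) < cc$survival_probs[r]
        prev <- prev & surv
        alive[, r] <- prev
      }
      gfp <- rep(NA, cfg$n_lines)
      final <- alive[, R]
      gfp[final] <- stats::runif(sum(final)) < cc$gfp_prob
      pl <- data.frame(
        line_id = sprintf("%s_%s_e%d_L%03d", cc$construct, cc$strain, e,
                          seq_len(cfg$n_lines)),
        construct = cc$construct, strain = cc$strain,
        selection = cc$selection, experiment_id = e,
        stringsAsFactors = FALSE)
      for (r in seq_len(R)) pl[[paste0("viable_r", r)]] <- alive[, r]
      pl$gfp <- gfp
      plates[[length(plates) + 1]] <- pl
    }
  }
  truth <- do.call(rbind, lapply(cfg$constructs, function(cc) {
    data.frame(construct = cc$construct, strain = cc$strain,
               selection = cc$selection,
               efficiency_mean = cc$efficiency_mean,
               marginal_final_viability = prod(cc$survival_probs),
               gfp_prob = cc$gfp_prob, stringsAsFactors = FALSE)
  }))
  truth$seed <- seed
  list(plates = do.call(rbind, plates),
       colonies = do.call(rbind, colonies),
       truth = truth)
}

#' Write / read plate-record and colony-count tables as TSV
#'
#' @param x Data frame (`plates` or `colonies` from [gen_screen()]).
#' @param path TSV path.
#' @return `path` (write) or the validated data frame (read).
#' @export
write_screen_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_screen_table
#' @export
read_plate_records <- function(path) {
  rec <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (cl in viability_columns(rec)) rec[[cl]] <- as.logical(rec[[cl]])
  rec$gfp <- as.logical(rec$gfp)
  validate_plate_records(rec)
}

#' @rdname write_screen_table
#' @export
read_colony_counts <- function(path) {
  cnt <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("construct", "strain", "experiment_id", "colonies", "dna_ug")
  missing <- setdiff(needed, colnames(cnt))
  if (length(missing) > 0) {
    stop("colony table missing column(s): ", paste(missing, collapse = ", "))
  }
  cnt
}
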