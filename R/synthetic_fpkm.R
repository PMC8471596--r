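#' Configuration for the synthetic diurnal FPKM generator
#'
#' Emulates a diurnal RNA-seq expression matrix: log-normal baseline means
#' across genes (expression spans orders of magnitude), a per-gene sinusoidal
#' diurnal component with random amplitude and phase over a 24-h cycle, and
#' multiplicative noise. Values are truncated at zero after noise.
#'
#' @param n_genes Number of genes.
#' @param n_timepoints Timepoints over the 24-h cycle (default 12, i.e.
#'   2-hourly).
#' @param meanlog,sdlog Log-normal parameters for baseline gene means.
#' @param amplitude_range Uniform range for the relative diurnal amplitude
#'   (0 = flat, 1 = mean-to-zero swing).
#' @param noise_cv Coefficient of variation of multiplicative Gaussian
#'   noise (default 0.1).
#' @return An `FpkmGenConfig` list.
#' @export
fpkm_config <- function(n_genes = 1000, n_timepoints = 12,
                        meanlog = 2, sdlog = 2,
                        amplitude_range = c(0, 0.8), noise_cv = 0.1) {
  stopifnot(n_genes >= 1, n_timepoints >= 1, noise_cv >= 0)
  structure(list(n_genes = n_genes, n_timepoints = n_timepoints,
                 meanlog = meanlog, sdlog = sdlog,
                 amplitude_range = amplitude_range, noise_cv = noise_cv),
            class = "FpkmGenConfig")
}

#' Generate a synthetic diurnal FPKM matrix with truth ranks
#'
#' @param cfg An `FpkmGenConfig` from [fpkm_config()].
#' @param seed Integer RNG seed (fixed seed gives identical output).
#' @param path Optional TSV path; when supplied the matrix is written in the
#'   format [load_fpkm()] reads.
#' @return List `matrix` (an `ExpressionMatrix`), `truth` (data frame
#'   `gene_id`, `true_mean`, `true_rank`; rank 1 = highest planted baseline
#'   mean) and `path` (`NULL` unless written).
#' @export
gen_fpkm <- function(cfg = fpkm_config(), seed = 1, path = NULL) {
  stopifnot(inherits(cfg, "FpkmGenConfig"))
  set.seed(seed)
  genes <- sprintf("SYNG%04d", seq_len(cfg$n_genes))
  mu <- stats::rlnorm(cfg$n_genes, cfg$meanlog, cfg$sdlog)
  amp <- stats::runif(cfg$n_genes, cfg$amplitude_range[1], cfg$amplitude_range[2])
  phase <- stats::runif(cfg$n_genes, 0, 2 * pi)
  hours <- seq(0, 24, length.out = cfg$n_timepoints + 1)[seq_len(cfg$n_timepoints)]
  base <- outer(seq_len(cfg$n_genes), seq_along(hours), function(i, j) {
    mu[i] * (1 + amp[i] * sin(2 * pi * hours[j] / 24 + phase[i]))
  })
  noise <- matrix(stats::rnorm(length(base), mean = 1, sd = cfg$noise_cv),
                  nrow = nrow(base))
  values <- pmax(base * noise, 0)
  dimnames(values) <- list(genes, sprintf("h%02g", hours))
  m <- structure(list(genes = genes, timepoints = colnames(values),
                      values = values), class = "ExpressionMatrix")
  truth <- data.frame(gene_id = genes, true_mean = mu,
                      true_rank = as.integer(rank(-mu, ties.method = "min")),
                      stringsAsFactors = FALSE)
  if (!is.null(path)) write_fpkm(m, path)
  list(matrix = m, truth = truth, path = path)
}
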