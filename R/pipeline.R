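#' Build a pipeline run configuration
#'
#' All defaults are echoed into the run report so that no silent parameter
#' exists. Stages: `simulate` (generate genome, FPKM matrix and screen data
#' with the packaged parameters), `features` (annotation statistics),
#' `rank` (expression ranking), `select` (terminator-part candidates, with
#' domestication), `screen` (plate-screen analytics).
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param stages Character vector of stages to run, in dependency order.
#' @param seed Integer seed governing every stochastic stage.
#' @param genome_cfg,fpkm_cfg,screen_cfg Generator configurations; defaults
#'   are [genome_config()], [fpkm_config()] and [published_screen_preset()].
#' @param max_rank,max_len,exceptions Selection rules for terminator
#'   candidates.
#' @param baseline Baseline construct for the screen comparisons.
#' @param alpha Significance level for the Mann-Whitney comparisons.
#' @param binsize Histogram bin width (bp).
#' @return A `RunConfig` list.
#' @export
run_config <- function(out_dir = tempfile("termpart_run"),
                       stages = c("simulate", "features", "rank", "select",
                                  "screen"),
                       seed = 1,
                       genome_cfg = genome_config(),
                       fpkm_cfg = NULL,
                       screen_cfg = published_screen_preset(),
                       max_rank = 350, max_len = 1000,
                       exceptions = character(),
                       baseline = "RBCS2", alpha = 0.05, binsize = 100) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (is.null(fpkm_cfg)) {
    fpkm_cfg <- fpkm_config(n_genes = genome_cfg$n_genes)
  }
  structure(list(out_dir = out_dir, stages = stages, seed = seed,
                 genome_cfg = genome_cfg, fpkm_cfg = fpkm_cfg,
                 screen_cfg = screen_cfg, max_rank = max_rank,
                 max_len = max_len, exceptions = exceptions,
                 baseline = baseline, alpha = alpha, binsize = binsize),
            class = "RunConfig")
}

#' Run the end-to-end synthetic pipeline
#'
#' Executes the configured stages in dependency order: simulate a genome,
#' expression matrix and screen dataset; compute annotation feature
#' statistics; rank expression; select and domesticate terminator-part
#' candidates; analyse the screen. A failure in one stage stops dependent
#' stages with a clear message. Every output file is listed in the report
#' manifest with its md5 checksum; rerunning with an identical config and
#' seed reproduces identical content.
#'
#' @param cfg A `RunConfig` from [run_config()].
#' @return A `RunReport`: list with `config` echo, per-stage `status`,
#'   `headline` numbers (medians, class counts, screen summary) and a file
#'   `manifest` (`path`, `md5`). Also written as JSON to
#'   `<out_dir>/report.json`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  status <- list()
  headline <- list()
  files <- character(0)

  genome <- NULL
  models <- NULL
  ranks <- NULL

  if ("simulate" %in% cfg$stages) {
    genome <- gen_genome(cfg$genome_cfg, seed = cfg$seed,
                         dir = cfg$out_dir, prefix = "genome")
    fp <- file.path(cfg$out_dir, "fpkm.tsv")
    fpkm <- gen_fpkm(cfg$fpkm_cfg, seed = cfg$seed + 1, path = fp)
    scr <- gen_screen(cfg$screen_cfg, seed = cfg$seed + 2)
    write_screen_table(scr$plates, file.path(cfg$out_dir, "plates.tsv"))
    write_screen_table(scr$colonies, file.path(cfg$out_dir, "colonies.tsv"))
    files <- c(files, genome$fasta, genome$gff3, fp,
               file.path(cfg$out_dir, c("plates.tsv", "colonies.tsv")))
    status$simulate <- "ok"
  }

  if ("features" %in% cfg$stages) {
    if (is.null(genome)) stop("features stage needs the simulate stage (or supply files)")
    models <- parse_gff3(genome$gff3)
    fl <- feature_lengths(models, "utr3")
    hist <- length_histogram(fl$length, cfg$binsize)
    med <- summarize_lengths(fl$length)
    dist <- intergenic_distances(models, "utr_to_utr")
    fpath <- file.path(cfg$out_dir, "utr3_lengths.tsv")
    hpath <- file.path(cfg$out_dir, "utr3_histogram.tsv")
    utils::write.table(cbind(fl, class = as.character(classify_length(fl$length))),
                       fpath, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(hist), hpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, fpath, hpath)
    headline$utr3 <- list(n = med$n, median_bp = med$median,
                          fraction_above_1kb = med$fraction_above,
                          class_counts = as.list(table(classify_length(fl$length))),
                          median_intergenic_bp =
                            if (nrow(dist) > 0) summarize_lengths(dist$distance)$median else NA)
    status$features <- "ok"
  }

  if ("rank" %in% cfg$stages) {
    fp <- file.path(cfg$out_dir, "fpkm.tsv")
    if (!file.exists(fp)) stop("rank stage: FPKM file not found: ", fp)
    ranks <- rank_expression(load_fpkm(fp))
    rpath <- file.path(cfg$out_dir, "rank_table.tsv")
    utils::write.table(ranks, rpath, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, rpath)
    headline$rank <- list(n_genes = nrow(ranks),
                          top_gene = ranks$gene_id[1],
                          top_mean_fpkm = ranks$mean_fpkm[1])
    status$rank <- "ok"
  }

  if ("select" %in% cfg$stages) {
    if (is.null(models) || is.null(ranks)) {
      stop("select stage needs the features and rank stages")
    }
    parts <- select_candidates(models, genome$fasta, ranks,
                               max_rank = cfg$max_rank,
                               exceptions = cfg$exceptions,
                               max_len = cfg$max_len)
    parts <- lapply(parts, domesticate)
    ppath <- file.path(cfg$out_dir, "parts.tsv")
    utils::write.table(parts_table(parts), ppath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (length(parts) > 0) {
      fpath <- file.path(cfg$out_dir, "parts.fasta")
      write_parts_fasta(parts, fpath)
      files <- c(files, fpath)
    }
    files <- c(files, ppath)
    headline$select <- list(n_candidates = length(parts),
                            classes = as.list(table(parts_table(parts)$size_class)))
    status$select <- "ok"
  }

  if ("screen" %in% cfg$stages) {
    pp <- file.path(cfg$out_dir, "plates.tsv")
    cp <- file.path(cfg$out_dir, "colonies.tsv")
    if (!file.exists(pp) || !file.exists(cp)) {
      stop("screen stage: plate/colony tables not found in ", cfg$out_dir)
    }
    plates <- read_plate_records(pp)
    counts <- read_colony_counts(cp)
    summ <- screen_summary(plates, counts)
    eff_values <- do.call(rbind, lapply(split(counts, counts$construct), function(g) {
      per <- tapply(g$colonies / g$dna_ug, g$experiment_id, mean)
      data.frame(construct = g$construct[1],
                 experiment_id = names(per), value = as.numeric(per),
                 stringsAsFactors = FALSE)
    }))
    tests <- if (cfg$baseline %in% eff_values$construct) {
      compare_constructs(eff_values, cfg$baseline, alpha = cfg$alpha)
    } else NULL
    spath <- file.path(cfg$out_dir, "screen_summary.tsv")
    bpath <- file.path(cfg$out_dir, "bubble_summary.tsv")
    utils::write.table(as.data.frame(summ), spath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(bubble_summary(summ), bpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, spath, bpath)
    if (!is.null(tests)) {
      tpath <- file.path(cfg$out_dir, "construct_tests.tsv")
      utils::write.table(tests, tpath, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, tpath)
    }
    headline$screen <- lapply(seq_len(nrow(summ)), function(i) as.list(summ[i, ]))
    status$screen <- "ok"
  }

  manifest <- data.frame(path = files,
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  report <- structure(list(config = echo_config(cfg), status = status,
                           headline = headline, manifest = manifest),
                      class = "RunReport")
  jsonlite::write_json(list(config = report$config, status = status,
                            headline = headline, manifest = manifest),
                       file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

echo_config <- function(cfg) {
  list(out_dir = cfg$out_dir, stages = cfg$stages, seed = cfg$seed,
       max_rank = cfg$max_rank, max_len = cfg$max_len,
       exceptions = cfg$exceptions, baseline = cfg$baseline,
       alpha = cfg$alpha, binsize = cfg$binsize,
       n_genes = cfg$genome_cfg$n_genes,
       screen_constructs = vapply(cfg$screen_cfg$constructs, `[[`,
                                  character(1), "construct"))
}

#' @export
print.RunReport <- function(x, ...) {
  cat("termpart pipeline run\n")
  cat("  stages:", paste(names(x$status), collapse = ", "), "\n")
  cat("  outputs:", nrow(x$manifest), "file(s) in", x$config$out_dir, "\n")
  invisible(x)
}
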