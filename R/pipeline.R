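#' Pipeline configuration
#'
#' Collects every tunable of the analysis in one object; each default
#' equals the default of the function that owns the parameter.
#'
#' @param table path to the peptide table.
#' @param design path to the design TSV.
#' @param fasta path to the protein FASTA.
#' @param protein accession of the target protein (default: first
#'   sequence of the FASTA).
#' @param out_dir output directory (created if needed).
#' @param dialect peptide-table dialect, `"generic"` or `"maxquant"`.
#' @param contaminant_patterns substrings marking contaminant entries.
#' @param alpha significance level for the depleted-peptide call.
#' @param floor_factor zero-imputation floor factor.
#' @param p_floor P-value clamp for the score.
#' @param test_scale `"linear"` or `"log"` t-test scale.
#' @param multimap_policy `"all"`, `"drop"`, or `"split"`.
#' @param spans,bass smoother settings.
#' @param threshold_quantile,min_length,merge_gap segment calling.
#' @param make_plot write the residue-track plot (default `TRUE`).
#' @export
rbrid_config <- function(table, design, fasta, protein = NULL, out_dir,
                         dialect = "generic",
                         contaminant_patterns = c("CON__", "REV__"),
                         alpha = 0.1, floor_factor = 0.5, p_floor = 1e-15,
                         test_scale = "linear", multimap_policy = "all",
                         spans = c(0.05, 0.2, 0.5), bass = 0,
                         threshold_quantile = 0.85, min_length = 10L,
                         merge_gap = 5L, make_plot = TRUE) {
  structure(as.list(environment()), class = "rbrid_config")
}

#' Run the full RBR-ID analysis
#'
#' Orchestrates read -> contaminant filter -> run-sum normalization ->
#' per-peptide statistics -> residue projection -> smoothing -> segment
#' calling, and writes `peptide_stats.tsv`, `residue_profile.tsv`,
#' `segments.tsv`, `profile.png` (optional) and `report.json` to the
#' output directory. On any failure, partial outputs are removed.
#'
#' @param config a [rbrid_config()].
#' @return (Invisibly) the run report: stage counts and the parameters
#'   used.
#' @export
run_rbrid <- function(config) {
  stopifnot(inherits(config, "rbrid_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  out <- function(name) {
    p <- file.path(config$out_dir, name)
    written <<- c(written, p)
    p
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
    })
  }

  peptides <- run_stage("read", read_peptide_table(config$table, config$dialect))
  design <- run_stage("read", read_design(config$design))
  proteins <- run_stage("read", read_protein_fasta(config$fasta))
  acc <- if (is.null(config$protein)) names(proteins)[1L] else config$protein
  if (!acc %in% names(proteins)) {
    stop(sprintf("[read] protein '%s' not in FASTA", acc), call. = FALSE)
  }
  target <- proteins[[acc]]

  n_read <- nrow(peptides)
  peptides <- run_stage("filter",
                        filter_contaminants(peptides, config$contaminant_patterns))
  n_retained <- nrow(peptides)

  peptides <- run_stage("normalize", normalize_run_intensities(peptides, design))
  stats <- run_stage("stats", peptide_stats(
    peptides, design, alpha = config$alpha,
    floor_factor = config$floor_factor, p_floor = config$p_floor,
    test_scale = config$test_scale))
  n_tested <- nrow(stats)
  n_significant <- sum(stats$significant)

  located <- run_stage("project", locate_peptides(stats, target))
  profile <- run_stage("project", residue_score_profile(
    located, nchar(target), config$multimap_policy))
  profile <- run_stage("smooth", smooth_profile(
    profile, spans = config$spans, bass = config$bass))
  segments <- run_stage("call", call_rbr_segments(
    profile, config$threshold_quantile, config$min_length, config$merge_gap))

  run_stage("write", {
    write_tsv <- function(df, name) {
      write.table(df, out(name), sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_tsv(as.data.frame(stats), "peptide_stats.tsv")
    prof_out <- data.frame(accession = acc, as.data.frame(profile))
    write_tsv(prof_out, "residue_profile.tsv")
    seg_out <- if (nrow(segments) > 0L) {
      data.frame(accession = acc, segments)
    } else {
      data.frame(accession = character(0), segments)
    }
    write_tsv(seg_out, "segments.tsv")
    if (isTRUE(config$make_plot)) {
      p <- plot_residue_profile(profile, segments, accession = acc)
      ggplot2::ggsave(out("profile.png"), p, width = 9, height = 4, dpi = 120)
    }
  })

  report <- list(
    protein = acc,
    protein_length = nchar(target),
    n_peptides_read = n_read,
    n_contaminants_removed = n_read - n_retained,
    n_peptides_retained = n_retained,
    n_peptides_tested = n_tested,
    n_peptides_dropped_undetected = n_retained - n_tested,
    n_significant = n_significant,
    n_located = length(unique(located$peptide)),
    n_segments = nrow(segments),
    segments = segments,
    parameters = config[setdiff(names(config),
                                c("table", "design", "fasta", "out_dir"))]
  )
  run_stage("write", {
    jsonlite::write_json(report, out("report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  invisible(report)
}

#' Simulate an experiment and write it to disk
#'
#' Generates a protein (unless given), plants an RBR, simulates the
#' replicated +/-4SU intensity table, and writes `peptides.tsv`
#' (generic dialect), `design.tsv`, `protein.fa` and `truth.tsv` —
#' files that [run_rbrid()] consumes directly.
#'
#' @param out_dir output directory.
#' @param seed integer seed (mandatory; the whole dataset is a pure
#'   function of it).
#' @param protein_length protein length (default 2500 residues,
#'   comparable to ATRX's 2492).
#' @param rbr a [planted_rbr()]; the default plants a 300-residue
#'   region at residues 1101-1400 with depletion factor 0.5.
#' @param config a [simulation_config()].
#' @param accession accession for the synthetic protein.
#' @return (Invisibly) the simulation (see [simulate_experiment()]),
#'   with `$protein` added.
#' @export
run_simulate <- function(out_dir, seed, protein_length = 2500L,
                         rbr = planted_rbr(1101L, 1400L, 0.5),
                         config = simulation_config(), accession = "SYN1") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  protein <- generate_protein_sequence(protein_length, seed)
  sim <- simulate_experiment(protein, rbr, config, seed = seed,
                             accession = accession)
  sim$protein <- protein

  write_peptide_table(sim$peptides, file.path(out_dir, "peptides.tsv"))
  write.table(as.data.frame(sim$design), file.path(out_dir, "design.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(paste0(">", accession), protein),
             file.path(out_dir, "protein.fa"))
  write.table(
    data.frame(start = rbr$start, end = rbr$end,
               delta = rbr$depletion_factor, seed = as.integer(seed)),
    file.path(out_dir, "truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(sim)
}

#' Plot a residue-level RBR-ID score track
#'
#' Raw summed scores as a light line, the super-smoothed track on top,
#' and called segments shaded.
#'
#' @param profile a smoothed `"rbrid_profile"`.
#' @param segments optional output of [call_rbr_segments()].
#' @param accession label for the title.
#' @return A ggplot object.
#' @export
plot_residue_profile <- function(profile, segments = NULL, accession = "") {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$position))
  if (!is.null(segments) && nrow(segments) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = segments,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, fill = "#2ca02c", alpha = 0.15,
      inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_line(ggplot2::aes(y = .data$raw_score),
                       color = "grey70", linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed_score),
                       color = "#1f77b4", linewidth = 0.7) +
    ggplot2::labs(x = "residue", y = "RBR-ID score",
                  title = if (nzchar(accession))
                    paste0("Residue-level RBR-ID score: ", accession) else NULL) +
    ggplot2::theme_minimal()
}
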