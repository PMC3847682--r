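#' Orthologous-group assembly pipeline
#'
#' Runs repeat filtering + read binning, per-bin sub-assembly and
#' copy-number estimation in one call.
#'
#' @param reads [seq_records()] shotgun reads.
#' @param ogrs [seq_records()] OGR template proteins.
#' @param bin_cfg [binning_config()].
#' @param asm_cfg [assembly_config()].
#' @param C covered-template fraction for copy-number calls.
#' @param repeat_library optional [seq_records()] repeat library.
#' @param subject_species species key(s) for identity thresholds.
#' @return list with `bins` ([bin_reads()] result), `subassemblies`,
#'   `assembly_stats` and `copy_numbers`.
#' @export
run_gene_pipeline <- function(reads, ogrs, bin_cfg = binning_config(),
                              asm_cfg = assembly_config(), C = 0.9,
                              repeat_library = NULL,
                              subject_species = "default") {
  bins <- bin_reads(reads, ogrs, bin_cfg, repeat_library,
                    subject_species)
  kept <- attr(bins, "reads_kept")
  sub_list <- list()
  stat_list <- list()
  for (bn in names(bins$bins)) {
    rd <- kept[kept$id %in% bins$bins[[bn]], , drop = FALSE]
    rownames(rd) <- NULL
    res <- assemble_bin(rd, asm_cfg, bin_id = bn)
    sub_list[[bn]] <- res$subassemblies
    stat_list[[bn]] <- res$stats
  }
  subassemblies <- if (length(sub_list)) do.call(rbind, sub_list) else
    data.frame(id = character(0), seq = character(0),
               kind = character(0), bin = character(0),
               stringsAsFactors = FALSE)
  rownames(subassemblies) <- NULL
  stats <- if (length(stat_list)) do.call(rbind, stat_list) else NULL
  cn <- estimate_copy_numbers(subassemblies, ogrs, C = C, cfg = bin_cfg,
                              subject_species = subject_species)
  list(bins = bins, subassemblies = subassemblies,
       assembly_stats = stats, copy_numbers = cn)
}

.modal_value <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

#' Polyploid gene-catalogue calibration experiment
#'
#' Builds a synthetic transcript set, replicates it into a homeolog
#' catalogue with the configured SNV rates, simulates shotgun reads,
#' runs the orthologous assembly pipeline at the requested minimum
#' overlap identity and compares estimated copy numbers to the
#' pre-replication copy count of each transcript.
#'
#' @param n_genes number of source transcripts.
#' @param cfg [sim_config()] (its seed drives everything).
#' @param mi minimum overlap identity (percent) for sub-assembly.
#' @param C covered-template fraction for copy-number estimation.
#' @param bin_cfg [binning_config()].
#' @param collapse_truth collapse catalogue copies at `mi/100` global
#'   identity before truth counting, so copies the assembler could never
#'   separate are not counted as distinct.
#' @return data.frame (ogr_id, estimated, true_copies, baseline = 1,
#'   ratio = estimated / baseline); attributes `modal_ratio` and
#'   `pipeline`.
#' @export
calibrate_polyploid <- function(n_genes = 200L, cfg = sim_config(),
                                mi = 99, C = 0.9,
                                bin_cfg = binning_config(repeat_filter = FALSE),
                                collapse_truth = TRUE) {
  gs <- generate_gene_space(n_genes, seed = cfg$seed)
  tx <- gene_transcripts(gs)
  cat0 <- make_polyploid_catalogue(tx$records, tx$coding, cfg)
  reads <- simulate_reads(cat0$catalogue,
                          sim_config(coverage = cfg$coverage,
                                     error_rate = cfg$error_rate,
                                     read_len_mean = cfg$read_len_mean,
                                     read_len_sd = cfg$read_len_sd,
                                     seed = cfg$seed + 7L))
  ogrs <- seq_records(gs$genes$gene_id, gs$genes$protein)
  pipe <- run_gene_pipeline(reads, ogrs, bin_cfg,
                            assembly_config(mi = mi), C = C)
  truth <- if (collapse_truth) truth_table(cat0, mi / 100) else
    truth_table(cat0)
  cn <- pipe$copy_numbers
  merged <- merge(cn[, c("ogr_id", "copy_number")], truth, by = "ogr_id")
  merged$baseline <- 1L
  merged$ratio <- merged$copy_number / merged$baseline
  names(merged)[names(merged) == "copy_number"] <- "estimated"
  attr(merged, "modal_ratio") <- .modal_value(merged$ratio)
  attr(merged, "pipeline") <- pipe
  merged
}

#' Diploid whole-genome shotgun calibration experiment
#'
#' Builds a synthetic repeat-containing genome with known gene-family
#' sizes, simulates whole-genome shotgun reads, runs repeat filtering,
#' binning to one OGR per family, sub-assembly and copy-number
#' estimation, and compares estimates to the true family sizes.
#'
#' @param n_genes total gene count.
#' @param multi_copy_fraction fraction of families given extra copies.
#' @param extra_copies copies added to each multi-copy family.
#' @param cfg [sim_config()].
#' @param mi minimum overlap identity (percent).
#' @param C covered-template fraction.
#' @param repeat_fraction repeat content of intergenic space.
#' @param intergenic_len_range intergenic spacer lengths (bp).
#' @return data.frame (ogr_id, estimated, true_copies, ratio);
#'   attributes `modal_ratio` and `pipeline`.
#' @export
calibrate_diploid <- function(n_genes = 200L, multi_copy_fraction = 0.2,
                              extra_copies = 1L, cfg = sim_config(),
                              mi = 99, C = 0.9, repeat_fraction = 0.4,
                              intergenic_len_range = c(300L, 900L)) {
  # multi_copy_fraction of the genes sit in families of 1 + extra_copies
  n_fam_multi <- floor(n_genes * multi_copy_fraction / (1 + extra_copies))
  fam <- c(rep(1L + extra_copies, n_fam_multi),
           rep(1L, n_genes - n_fam_multi * (1L + extra_copies)))
  gs <- generate_gene_space(n_genes, family_sizes = fam,
                            repeat_fraction = repeat_fraction,
                            intergenic_len_range = intergenic_len_range,
                            seed = cfg$seed)
  reads <- simulate_reads(gs$chromosome,
                          sim_config(coverage = cfg$coverage,
                                     error_rate = cfg$error_rate,
                                     read_len_mean = cfg$read_len_mean,
                                     read_len_sd = cfg$read_len_sd,
                                     seed = cfg$seed + 7L))
  # one OGR per family: the first copy's protein
  first <- gs$genes[gs$genes$copy == 1L, , drop = FALSE]
  ogrs <- seq_records(first$family_id, first$protein)
  truth <- data.frame(ogr_id = first$family_id,
                      true_copies = as.integer(table(
                        gs$genes$family_id)[first$family_id]),
                      stringsAsFactors = FALSE)
  pipe <- run_gene_pipeline(reads, ogrs,
                            binning_config(repeat_filter = TRUE),
                            assembly_config(mi = mi), C = C,
                            repeat_library = gs$repeats)
  cn <- pipe$copy_numbers
  merged <- merge(cn[, c("ogr_id", "copy_number")], truth, by = "ogr_id")
  merged$ratio <- merged$copy_number / merged$true_copies
  names(merged)[names(merged) == "copy_number"] <- "estimated"
  attr(merged, "modal_ratio") <- .modal_value(merged$ratio)
  attr(merged, "pipeline") <- pipe
  merged
}

#' Copy-number and assembly-fraction sweep over mi
#'
#' On one fixed binned read set, re-assembles and re-estimates at each
#' `mi`, reporting the per-mi median copy number and assembled-read
#' fraction (the stringency trade-off diagnostic).
#'
#' @param bins named list of [seq_records()] (reads per OGR bin).
#' @param ogrs [seq_records()] OGR proteins.
#' @param mi_values percent identities to sweep.
#' @param C covered-template fraction.
#' @param bin_cfg [binning_config()] HSP filters for re-alignment.
#' @return data.frame (mi, median_copy_number, frac_assembled).
#' @export
copy_number_sweep <- function(bins, ogrs, mi_values = c(97, 99, 100),
                              C = 0.9, bin_cfg = binning_config()) {
  rows <- list()
  for (mi in mi_values) {
    acfg <- assembly_config(mi = mi)
    subs <- list(); na <- 0L; ns <- 0L; ne <- 0L
    for (bn in names(bins)) {
      res <- assemble_bin(bins[[bn]], acfg, bin_id = bn)
      subs[[bn]] <- res$subassemblies
      na <- na + res$stats$n_assembled
      ns <- ns + res$stats$n_singleton
      ne <- ne + res$stats$n_excluded
    }
    subassemblies <- do.call(rbind, subs)
    cn <- estimate_copy_numbers(subassemblies, ogrs, C = C, cfg = bin_cfg)
    rows[[length(rows) + 1L]] <- data.frame(
      mi = mi,
      median_copy_number = stats::median(cn$copy_number),
      frac_assembled = if (na + ns + ne > 0) na / (na + ns + ne) else 0)
  }
  do.call(rbind, rows)
}
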