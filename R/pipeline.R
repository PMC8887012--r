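#' Pipeline run configuration
#'
#' Bundles every stage's parameters with defaults. Unknown arguments are
#' rejected (R refuses unused arguments), and [run_pipeline()] writes the
#' resolved configuration next to its outputs so a run can be reproduced
#' byte-for-byte.
#'
#' @param outdir output directory.
#' @param seed master seed; forwarded to the simulator.
#' @param sim a [sim_config()]; its seed is overridden by `seed`.
#' @param read_length mappability tile length (bp).
#' @param resolution Hi-C bin size (bp).
#' @param metaplot_W TSS metaplot half-window (bp).
#' @param vplot_W V-plot half-window (bp).
#' @param peak_window,peak_p peak caller window (bp) and p-value threshold.
#' @param dyad_window,dyad_step sliding-window size/step for dyad calling.
#' @param nuc_len_range,kernel_bw,threshold_mult,min_separation dyad-caller
#'   parameters (see [call_dyads()]).
#' @param log_level `"info"` or `"quiet"`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(outdir, seed = 1L, sim = NULL,
                       read_length = 36L, resolution = 5000L,
                       metaplot_W = 500L, vplot_W = 200L,
                       peak_window = 300L, peak_p = 1e-5,
                       dyad_window = 1000L, dyad_step = 500L,
                       nuc_len_range = c(160L, 250L), kernel_bw = 20,
                       threshold_mult = 2, min_separation = 120L,
                       log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (missing(outdir)) stop2("config is missing required key: outdir")
  sim <- sim %||% sim_config(seed = seed)
  sim$seed <- seed
  structure(as.list(environment()), class = "run_config")
}

pipeline_log <- function(cfg, stage, t0 = NULL) {
  if (cfg$log_level == "quiet") return(invisible(NULL))
  msg <- if (is.null(t0)) sprintf("[%s] ...", stage) else
    sprintf("[%s] done in %.1f s", stage, as.numeric(Sys.time() - t0,
                                                     units = "secs"))
  message(msg)
}

#' Run the full analysis pipeline on simulated data
#'
#' Chains simulate -> mappability -> enrichment/copy numbers -> fragment
#' spectra -> TSS metaplots and peaks -> dyads and V-plots -> Hi-C binning,
#' balancing, trans profiles and telomere scores. All stage outputs are
#' written under `config$outdir`; a machine-readable report (JSON) and the
#' resolved configuration are written alongside. Reruns with the same
#' configuration are byte-identical.
#'
#' @param config a [run_config()].
#' @return the report, invisibly (a named list).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop2("config must be a run_config")
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed)

  t0 <- Sys.time(); pipeline_log(config, "simulate")
  sim <- simulate_all(config$sim, outdir)
  genome <- sim$genome
  pipeline_log(config, "simulate", t0)

  t0 <- Sys.time(); pipeline_log(config, "mappability")
  track <- compute_mappability(genome, config$read_length)
  write_bedgraph(track, file.path(outdir, sprintf("mappability_%d.bedgraph",
                                                  config$read_length)))
  pipeline_log(config, "mappability", t0)

  t0 <- Sys.time(); pipeline_log(config, "enrichment")
  enr <- compute_enrichment(sim$atac, sim$input, genome, track,
                            group_by = "compartment")
  enr_kas <- compute_enrichment(sim$kas, sim$input, genome, track,
                                group_by = "compartment")
  enr_rdna <- compute_enrichment(sim$atac, sim$input, genome, track,
                                 group_by = "region_class")
  cn <- estimate_copy_numbers(sim$input, genome, track)
  write_tsv(enr, file.path(outdir, "enrichment_atac.tsv"))
  write_tsv(enr_kas, file.path(outdir, "enrichment_kas.tsv"))
  write_tsv(enr_rdna, file.path(outdir, "enrichment_rdna.tsv"))
  write_tsv(data.frame(chrom = names(cn), copy_number = unname(cn)),
            file.path(outdir, "copy_numbers.tsv"))
  report$atac_enrichment <- setNames(as.list(enr$enrichment), enr$group)
  report$kas_enrichment <- setNames(as.list(enr_kas$enrichment),
                                    enr_kas$group)
  report$rdna_enrichment <- setNames(as.list(enr_rdna$enrichment),
                                     enr_rdna$group)
  report$copy_numbers <- as.list(round(cn, 4))
  pipeline_log(config, "enrichment", t0)

  t0 <- Sys.time(); pipeline_log(config, "spectra")
  fractions <- compartment_read_fractions(sim$atac, genome)
  report$atac_compartment_fractions <- as.list(round(fractions, 5))
  modes <- list()
  for (comp in unique(genome$compartment)) {
    sp <- length_spectrum(sim$atac, genome, comp)
    md <- detect_modes(sp)
    modes[[comp]] <- md$mode
    write_tsv(data.frame(length = sp$length, density = sp$density),
              file.path(outdir, sprintf("fraglen_%s.tsv", comp)))
  }
  report$fragment_length_modes <- modes
  pipeline_log(config, "spectra", t0)

  t0 <- Sys.time(); pipeline_log(config, "tss")
  nm_genes <- genome$genes[genome$compartment[genome$genes$chrom] ==
                             "nucleomorph" & !genome$genes$is_rdna, ]
  nm_tss <- gene_tss(nm_genes)
  prof <- tss_profile(sim$atac, nm_tss, W = config$metaplot_W)
  write_tsv(data.frame(position = prof$positions, coverage = prof$metaplot),
            file.path(outdir, "metaplot_nucleomorph_tss.tsv"))
  peaks <- call_peaks_simple(sim$atac, genome, window = config$peak_window,
                             p_threshold = config$peak_p)
  if (nrow(peaks) > 0)
    write_tsv(peaks, file.path(outdir, "peaks.tsv"))
  all_tss <- gene_tss(genome$genes[!genome$genes$is_rdna, ])
  pd <- peak_tss_distances(peaks, all_tss)
  ctrl <- random_control_peaks(genome)
  pd_ctrl <- peak_tss_distances(ctrl, all_tss)
  write_tsv(pd, file.path(outdir, "peak_tss_distances.tsv"))
  write_tsv(pd_ctrl, file.path(outdir, "peak_tss_distances_control.tsv"))
  report$n_peaks <- nrow(peaks)
  report$metaplot_max_offset <- prof$positions[which.max(prof$metaplot)]
  pipeline_log(config, "tss", t0)

  t0 <- Sys.time(); pipeline_log(config, "nucleosomes")
  nm_chroms <- names(genome$sequences)[genome$compartment == "nucleomorph"]
  win_nm <- sliding_windows(genome, config$dyad_window, config$dyad_step,
                            chroms = nm_chroms)
  dy_nm <- call_dyads(sim$atac, win_nm, genome,
                      nuc_len_range = config$nuc_len_range,
                      kernel_bw = config$kernel_bw,
                      threshold_mult = config$threshold_mult,
                      min_separation = config$min_separation)
  nuc_genes <- genome$genes[genome$compartment[genome$genes$chrom] ==
                              "nucleus" & !genome$genes$is_rdna, ]
  win_nuc <- anchor_windows(genome, gene_tss(nuc_genes), config$dyad_window)
  dy_nuc <- call_dyads(sim$atac, win_nuc, genome,
                       nuc_len_range = config$nuc_len_range,
                       kernel_bw = config$kernel_bw,
                       threshold_mult = config$threshold_mult,
                       min_separation = config$min_separation)
  dyads <- rbind(dy_nm, dy_nuc)
  if (nrow(dyads) > 0) {
    bed <- data.frame(chrom = dyads$chrom, start = pmax(0L, dyads$pos - 5L),
                      end = dyads$pos + 6L, score = dyads$score)
    write_tsv(bed, file.path(outdir, "dyads.bed"))
  }
  vp <- make_vplot(sim$atac, dy_nm, W = config$vplot_W)
  vout <- data.table::as.data.table(vp$matrix, keep.rownames = "length")
  data.table::fwrite(vout, file.path(outdir, "vplot_nucleomorph.tsv"),
                     sep = "\t")
  dtd <- dyad_tss_distribution(dy_nm, nm_tss, W = config$metaplot_W)
  write_tsv(dtd, file.path(outdir, "dyad_tss_distribution.tsv"))
  report$n_dyads <- list(nucleomorph = nrow(dy_nm), nucleus = nrow(dy_nuc))
  rowmass <- rowSums(vp$matrix)
  report$vplot_modal_length <- if (vp$total > 0)
    as.integer(vp$lengths[which.max(rowmass)]) else NA
  pipeline_log(config, "nucleosomes", t0)

  t0 <- Sys.time(); pipeline_log(config, "hic")
  cmraw <- bin_contacts(sim$pairs, genome, config$resolution)
  cmkr <- balance(cmraw, "KR")
  write_contact_matrix(cmkr, file.path(outdir, "hic_kr.tsv"),
                       file.path(outdir, "hic_kr_weights.tsv"))
  tp <- lapply(c(NONE = "NONE", VC = "VC", VC_SQRT = "VC_SQRT", KR = "KR"),
               function(m) trans_profile(balance(cmraw, m), "chrM"))
  tp_all <- do.call(rbind, tp)
  write_tsv(tp_all, file.path(outdir, "trans_profile_chrM.tsv"))
  nm_tel <- genome$telomeres[genome$compartment[genome$telomeres$chrom] ==
                               "nucleomorph", ]
  tel <- telomere_network_score(cmraw, telomeres = nm_tel)
  report$telomere_network_ratio <- tel$ratio
  report$cis_end_fold <- as.list(round(tel$cis_end_fold, 3))
  report$chrM_trans_profile <- lapply(tp, function(x)
    setNames(as.list(signif(x$frequency, 6)), x$target))
  pipeline_log(config, "hic", t0)

  cfg_out <- config
  cfg_out$outdir <- NULL      # implied by file location; keeps reruns
  cfg_out$sim$chrom_plan <- as.list(cfg_out$sim$chrom_plan)  # byte-identical
  jsonlite::write_json(cfg_out, file.path(outdir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

#' Bundled demo configuration
#'
#' A reduced-size configuration for the end-to-end pipeline demo: the default
#' genome plan with lighter sequencing depths, so a full [run_pipeline()]
#' completes in well under ten minutes on one CPU.
#'
#' @param outdir output directory.
#' @param seed master seed.
#' @return a [run_config()].
#' @export
demo_config <- function(outdir = tempfile("nucleochrom_demo_"), seed = 1L) {
  sim <- sim_config(seed = seed,
                    depth = list(atac = 1e5, kas = 5e4, input = 1e5,
                                 hic = 5e4))
  run_config(outdir = outdir, seed = seed, sim = sim, log_level = "info")
}
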