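## End-to-end orchestration: configuration validation, deterministic staged
## seeding, the simulate -> build-db -> cluster -> assign -> quantify ->
## diversity -> evaluate workflow, and a checksummed manifest.

# named substreams: every random draw flows from one master seed
STAGE_OFFSETS <- c(references = 101L, reads = 211L, qpcr = 307L)

substream_seed <- function(master, stage) {
  (as.integer(master) * 1009L + STAGE_OFFSETS[[stage]]) %% 2147483647L
}

#' Build and validate a run configuration
#'
#' @param preset mock-community preset name (`"MC1"`..`"MC4"`).
#' @param out_dir output directory.
#' @param depth,error_rate,chimera_rate generator settings (see
#'   [mock_spec()]).
#' @param d clustering distance; `min_total` abundance threshold;
#'   `noise_sd` qPCR noise (Ct); `n_samples` replicate samples;
#'   `seed` master seed.
#' @param qpcr_file optional externally measured qPCR TSV
#'   (`sample, species, Ct, curve_id`) used instead of simulated qPCR.
#' @param config_file optional YAML file; values in the file are defaults
#'   that explicit arguments override.
#' @return validated config list (class `run_config`).
#' @export
run_config <- function(preset = "MC1", out_dir = tempfile("gyrbench_run_"),
                       depth = 50000L, error_rate = 1e-3,
                       chimera_rate = 0.012, d = 3L, min_total = 11L,
                       noise_sd = 0.5, n_samples = 1L, seed = 1L,
                       qpcr_file = NULL, config_file = NULL) {
  cfg <- list(preset = preset, out_dir = out_dir, depth = depth,
              error_rate = error_rate, chimera_rate = chimera_rate, d = d,
              min_total = min_total, noise_sd = noise_sd,
              n_samples = n_samples, seed = seed, qpcr_file = qpcr_file)
  if (!is.null(config_file)) {
    if (!file.exists(config_file))
      stop("config file not found: ", config_file, call. = FALSE)
    fromfile <- yaml::read_yaml(config_file)
    supplied <- names(as.list(match.call()))
    for (k in setdiff(names(fromfile), supplied)) cfg[[k]] <- fromfile[[k]]
  }
  if (!cfg$preset %in% c("MC1", "MC2", "MC3", "MC4"))
    stop("unknown preset: ", cfg$preset, call. = FALSE)
  if (!is.null(cfg$qpcr_file) && !file.exists(cfg$qpcr_file))
    stop("qPCR file not found: ", cfg$qpcr_file, call. = FALSE)
  stopifnot(cfg$depth > 0, cfg$d >= 0, cfg$min_total >= 0,
            cfg$noise_sd >= 0, cfg$n_samples >= 1)
  structure(cfg, class = "run_config")
}

write_stage_tsv <- function(df, path, seed) {
  con <- file(path, "w")
  writeLines(paste0("# seed: ", seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

#' Run the full mock-community pipeline
#'
#' Executes simulate -> build-db -> cluster -> assign -> quantify ->
#' diversity -> evaluate, writing every stage's tabular output plus an
#' md5-checksummed manifest. Re-running with the same configuration
#' reproduces byte-identical outputs; on failure a `FAILED` marker file is
#' left next to the partial outputs.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with the in-memory stage results and the
#'   manifest `data.frame(file, md5)`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  res <- tryCatch({
    spec <- mock_preset(config$preset, depth = config$depth,
                        error_rate = config$error_rate,
                        chimera_rate = config$chimera_rate, seed = seed)
    refs <- make_reference_set(spec, seed = substream_seed(seed, "references"))
    db <- build_database(markers_as_genome_records(refs))
    write_marker_fasta(db, file.path(config$out_dir, "db.fasta"),
                       file.path(config$out_dir, "db.tsv"))
    sim <- simulate_reads(spec, refs, n_samples = config$n_samples,
                          seed = substream_seed(seed, "reads"))
    write_read_fasta(sim$reads, file.path(config$out_dir, "reads"),
                     seed = seed)
    write_stage_tsv(sim$truth, file.path(config$out_dir, "truth.tsv"), seed)
    otus <- cluster_reads(sim$reads, d = config$d,
                          min_total = config$min_total)
    write_otutab(otus, file.path(config$out_dir, "otu_table.tsv"),
                 rep_fasta = file.path(config$out_dir, "otu_reps.fasta"),
                 seed = seed)
    assignments <- assign_taxonomy(otus, db)
    write_stage_tsv(assignments,
                    file.path(config$out_dir, "assignments.tsv"), seed)
    ratios <- paralog_ratios(assignments, otus, rank = "genus")
    write_stage_tsv(ratios, file.path(config$out_dir, "paralog_ratios.tsv"),
                    seed)
    qpcr <- if (!is.null(config$qpcr_file)) {
      read.delim(config$qpcr_file, comment.char = "#")
    } else {
      simulate_qpcr(sim$cfu, noise_sd = config$noise_sd,
                    seed = substream_seed(seed, "qpcr"))
    }
    write_stage_tsv(qpcr, file.path(config$out_dir, "qpcr.tsv"), seed)
    qrec <- quant_records(otus, assignments, qpcr)
    write_stage_tsv(qrec, file.path(config$out_dir, "quant_records.tsv"),
                    seed)
    fits <- fit_quant_strata(qrec)
    fit_df <- do.call(rbind, lapply(fits, function(f)
      data.frame(stratum = f$stratum, slope = f$slope,
                 intercept = f$intercept, r_squared = f$r_squared,
                 n = nrow(f$data))))
    devs <- do.call(rbind, lapply(fits, function(f) {
      d <- species_deviation(f); d$stratum <- f$stratum; d
    }))
    rownames(devs) <- NULL
    write_stage_tsv(fit_df, file.path(config$out_dir, "quant_fits.tsv"), seed)
    write_stage_tsv(devs, file.path(config$out_dir, "quant_deviations.tsv"),
                    seed)
    write_stage_tsv(rarefaction_curve(otus),
                    file.path(config$out_dir, "rarefaction.tsv"), seed)
    comp <- composition_table(otus, assignments, "phylum")
    write_stage_tsv(data.frame(taxon = rownames(comp), comp,
                               check.names = FALSE),
                    file.path(config$out_dir, "composition_phylum.tsv"), seed)
    if (config$n_samples >= 2L) {
      bc <- as.matrix(bray_curtis_matrix(otus))
      write_stage_tsv(data.frame(sample = rownames(bc), bc,
                                 check.names = FALSE),
                      file.path(config$out_dir, "bray_curtis.tsv"), seed)
      ord <- pcoa_ordination(bray_curtis_matrix(otus))
      write_stage_tsv(
        data.frame(sample = rownames(ord$coordinates), ord$coordinates,
                   check.names = FALSE),
        file.path(config$out_dir, "pcoa.tsv"), seed)
    }
    report <- composition_recovery(sim$truth, assignments, otus, "phylum")
    rich <- richness_recovery(sim$truth, otus, assignments)
    par_rec <- paralog_recovery(spec, assignments, otus)
    write_stage_tsv(report, file.path(config$out_dir, "report.tsv"), seed)
    write_stage_tsv(rich, file.path(config$out_dir, "report_richness.tsv"),
                    seed)
    write_stage_tsv(par_rec, file.path(config$out_dir, "report_paralog.tsv"),
                    seed)
    list(spec = spec, refs = refs, db = db, sim = sim, otus = otus,
         assignments = assignments, ratios = ratios, qpcr = qpcr,
         quant = qrec, fits = fits, deviations = devs, report = report,
         richness = rich, paralog = par_rec)
  }, error = function(e) {
    writeLines(conditionMessage(e), file.path(config$out_dir, "FAILED"))
    stop(e)
  })
  files <- sort(setdiff(list.files(config$out_dir, recursive = TRUE),
                        "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$out_dir, files))),
    stringsAsFactors = FALSE)
  params <- vapply(config[c("preset", "depth", "error_rate", "chimera_rate",
                            "d", "min_total", "noise_sd", "n_samples",
                            "seed")],
                   function(v) paste0(v), character(1L))
  con <- file(file.path(config$out_dir, "manifest.tsv"), "w")
  writeLines(c(paste0("# ", names(params), ": ", params),
               paste0("# gyrbench: ",
                      as.character(utils::packageVersion("gyrbench")))), con)
  write.table(manifest, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(list(results = res, manifest = manifest))
}
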