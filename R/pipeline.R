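# End-to-end orchestration: simulate -> search -> annotate ->
# frameshift/termini -> group -> EVE-screen -> quantify, with per-stage
# outputs and a consolidated JSON-able report.

#' Default pipeline configuration
#'
#' A single nested list carrying a `simulate` block (generator config +
#' seed) and one block per stage with the module defaults.  Any block can
#' be overridden; alternatively `inputs` can point at existing FASTA/TSV
#' files instead of `simulate`.
#'
#' @param seed Seed stored in the simulate block.
#' @param eve Plant an endogenous viral element (see [default_config()]).
#' @return Nested configuration list for [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L, eve = TRUE) {
  list(
    simulate = list(config = default_config(eve = eve), seed = seed),
    search = list(max_evalue = 1e-5, gap_open = 11, gap_extend = 1,
                  K = 0.041, lam = 0.267),
    annotate = list(min_aa = 100, both_strands = TRUE),
    frameshift = list(patterns = DEFAULT_SLIPPERY_PATTERNS),
    termini = list(w = 40, max_mismatch_run = 2, max_mismatches = 2),
    group = list(fpkm_min = 1, frag_min = 10, r_min = 0.8),
    eve_screen = list(k = 31, min_id = 0.90, min_len = 100, cov_min = 0.1),
    quantify = list()
  )
}

#' Run the full virome-discovery pipeline
#'
#' Stages run in order (simulate, search, annotate, frameshift, termini,
#' group, eve_screen, quantify); each stage's outputs are written under
#' `outdir` (when given) before the next stage starts, and everything is
#' aggregated into a report.  Deterministic for fixed config + seed.
#'
#' @param config Pipeline configuration ([default_pipeline_config()]), or
#'   a path to a YAML file with the same structure.
#' @param outdir Optional output directory for per-stage files.
#' @param seed Overrides the seed in the simulate block when not `NULL`.
#' @param verbose Log one line per stage (plus per-candidate traces).
#' @return Object of class `pipeline_report` (see Details) with
#'   per-candidate annotation, grouping, EVE verdicts and FPKM, plus run
#'   metadata (`config_hash`, `seed`, stage timings).
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir = NULL,
                         seed = NULL, verbose = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    config <- rebuild_config(config)
  }
  if (!is.null(seed)) config$simulate$seed <- seed
  cfg_hash <- config_hash(config)
  timings <- c()
  say <- function(...) if (verbose) message("[aranevir] ", ...)
  tic <- function() Sys.time()
  lap <- function(stage, t0) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)

  # --- stage: simulate (or load) ------------------------------------------
  t0 <- tic()
  if (!is.null(config$inputs)) {
    ins <- config$inputs
    for (f in unlist(ins[c("transcripts", "proteins")])) {
      if (!file.exists(f)) stop("missing input file: ", f)
    }
    transcripts <- as_named_seqs(ins$transcripts, "DNA")
    proteins <- as_named_seqs(ins$proteins, "AA")
    counts <- NULL
    if (!is.null(ins$counts)) {
      cts <- read.delim(ins$counts, check.names = FALSE)
      counts <- as.matrix(cts[, -1, drop = FALSE])
      rownames(counts) <- cts[[1]]
    }
    libs <- if (!is.null(ins$libraries)) read.delim(ins$libraries) else NULL
    design <- list(libraries = libs)
    genome <- if (!is.null(ins$genome)) as_named_seqs(ins$genome, "DNA")
    dna_reads <- if (!is.null(ins$dna_reads))
      as_named_seqs(ins$dna_reads, "DNA")
    dataset <- NULL
  } else {
    dataset <- build_dataset(config$simulate$config,
                             seed = config$simulate$seed)
    transcripts <- as_named_seqs(dataset$transcripts, "DNA")
    proteins <- as_named_seqs(dataset$proteins, "AA")
    counts <- dataset$counts
    design <- dataset$design
    genome <- as_named_seqs(dataset$host_genome, "DNA")
    dna_reads <- as_named_seqs(dataset$dna_reads, "DNA")
    if (!is.null(outdir)) write_dataset(dataset, file.path(outdir, "data"))
  }
  lap("simulate", t0)
  say("simulate: ", length(transcripts), " transcripts, ",
      length(proteins), " reference proteins")

  # --- stage: translated search -------------------------------------------
  t0 <- tic()
  hits <- if (length(transcripts)) {
    do.call(translated_search,
            c(list(transcripts = transcripts, protein_db = proteins),
              config$search))
  } else empty_hits()
  candidates <- collapse_hits(hits)
  cand_ids <- unique(candidates$candidate)
  if (!is.null(outdir)) {
    write.table(hits, file.path(outdir, "hits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(candidates, file.path(outdir, "candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  lap("search", t0)
  say("search: ", nrow(hits), " hits -> ", length(cand_ids), " candidates")

  # --- per-candidate stages ------------------------------------------------
  t0 <- tic()
  ann <- lapply(setNames(cand_ids, cand_ids), function(id) {
    orfs <- do.call(find_orfs, c(list(seq = transcripts[[id]]),
                                 config$annotate))
    say("  ", id, ": ", nrow(orfs), " ORF(s)")
    orfs
  })
  if (!is.null(outdir)) {
    dir.create(file.path(outdir, "orfs"), showWarnings = FALSE)
    for (id in cand_ids) {
      orfs_to_gff3(ann[[id]], id, file.path(outdir, "orfs",
                                            paste0(id, ".gff3")))
    }
  }
  lap("annotate", t0)

  t0 <- tic()
  fs <- lapply(setNames(cand_ids, cand_ids), function(id) {
    orfs <- ann[[id]]
    fwd <- orfs[orfs$orientation == "forward", , drop = FALSE]
    if (nrow(fwd) == 0L) return(NULL)
    do.call(find_slippery_sites,
            c(list(seq = transcripts[[id]], orf1a = fwd[1, ]),
              config$frameshift))
  })
  if (!is.null(outdir)) {
    fs_tab <- do.call(rbind, lapply(cand_ids, function(id) {
      if (is.null(fs[[id]]) || nrow(fs[[id]]) == 0) return(NULL)
      cbind(candidate = id, fs[[id]])
    }))
    if (is.null(fs_tab)) fs_tab <- data.frame(candidate = character(0))
    write.table(fs_tab, file.path(outdir, "frameshift_sites.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  lap("frameshift", t0)

  t0 <- tic()
  ph <- lapply(setNames(cand_ids, cand_ids), function(id) {
    s <- transcripts[[id]]
    w <- config$termini$w
    if (nchar(s) < 2 * w) return(NULL)
    do.call(panhandle_duplex,
            c(list(five_term = substr(s, 1, w),
                   three_term = substr(s, nchar(s) - w + 1, nchar(s))),
              config$termini))
  })
  if (!is.null(outdir)) {
    ph_tab <- do.call(rbind, lapply(cand_ids, function(id) {
      if (is.null(ph[[id]])) return(NULL)
      data.frame(candidate = id, duplex_len = ph[[id]]$duplex_len,
                 paired_fraction = round(ph[[id]]$paired_fraction, 4))
    }))
    if (is.null(ph_tab)) ph_tab <- data.frame(candidate = character(0))
    write.table(ph_tab, file.path(outdir, "panhandle.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  lap("termini", t0)

  # --- stage: grouping ------------------------------------------------------
  t0 <- tic()
  groups <- NULL
  if (!is.null(counts) && length(cand_ids) > 0 &&
      all(cand_ids %in% rownames(counts))) {
    prof <- expression_profiles(
      counts[cand_ids, , drop = FALSE],
      lengths = setNames(nchar(transcripts[cand_ids]), cand_ids),
      host_mapped_reads = setNames(design$libraries$host_mapped_reads,
                                   design$libraries$library_id),
      fpkm_min = config$group$fpkm_min, frag_min = config$group$frag_min)
    groups <- group_segments(prof, r_min = config$group$r_min)
    if (!is.null(outdir)) {
      write.table(groups, file.path(outdir, "groups.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  lap("group", t0)
  say("group: ", length(unique(groups$group_id)), " group(s)")

  # --- stage: EVE screening -------------------------------------------------
  t0 <- tic()
  read_kmers <- if (!is.null(dna_reads) && length(dna_reads)) {
    dna_read_kmers(dna_reads, k = config$eve_screen$k)
  }
  verdicts <- lapply(setNames(cand_ids, cand_ids), function(id) {
    ev <- integration_evidence(transcripts[[id]], genome = genome,
                               dna_reads = read_kmers,
                               k = config$eve_screen$k,
                               min_id = config$eve_screen$min_id,
                               min_len = config$eve_screen$min_len,
                               cov_min = config$eve_screen$cov_min)
    list(evidence = ev, verdict = classify_exogenous(ev))
  })
  lap("eve_screen", t0)

  # --- stage: quantification ------------------------------------------------
  t0 <- tic()
  quant <- NULL
  if (!is.null(counts) && length(cand_ids) > 0 &&
      all(cand_ids %in% rownames(counts))) {
    tab <- fpkm_table(counts,
                      lengths = setNames(nchar(transcripts), names(transcripts)),
                      design = design, viral_ids = cand_ids)
    seg_virus <- setNames(groups$group_id, groups$segment_id)
    quant <- list(table = tab,
                  summary = summarize_profiles(tab, design, seg_virus))
    if (!is.null(outdir)) {
      write.table(data.frame(segment = rownames(tab$fpkm), tab$fpkm,
                             check.names = FALSE),
                  file.path(outdir, "fpkm.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
  }
  lap("quantify", t0)

  # --- report ---------------------------------------------------------------
  per_candidate <- lapply(setNames(cand_ids, cand_ids), function(id) {
    best <- candidates[candidates$candidate == id, ][1, ]
    list(candidate = id,
         best_hit = list(ref = best$ref, evalue = best$evalue,
                         pident = best$pident, frame = best$frame),
         taxonomy_hint = best$ref,
         orfs = ann[[id]][, setdiff(names(ann[[id]]), "protein")],
         frameshift_sites = fs[[id]],
         panhandle = if (!is.null(ph[[id]]))
           list(duplex_len = ph[[id]]$duplex_len,
                paired_fraction = ph[[id]]$paired_fraction),
         group_id = if (!is.null(groups))
           groups$group_id[match(id, groups$segment_id)],
         eve_verdict = verdicts[[id]]$verdict,
         dna_covered_fraction = verdicts[[id]]$evidence$dna_covered_fraction,
         fpkm = if (!is.null(quant)) as.list(quant$table$fpkm[id, ]))
  })
  report <- structure(list(
    candidates = per_candidate,
    groups = groups,
    totals = if (!is.null(quant)) quant$summary$percent_viral,
    tissue_means = if (!is.null(quant)) quant$summary$tissue_means,
    metadata = list(config_hash = cfg_hash,
                    seed = config$simulate$seed %||% NA,
                    n_transcripts = length(transcripts),
                    n_hits = nrow(hits),
                    n_candidates = length(cand_ids),
                    stage_seconds = as.list(timings))),
    class = "pipeline_report")
  if (!is.null(outdir)) {
    jsonlite::write_json(report_to_json(report),
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  attr(report, "dataset") <- dataset
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report:", x$metadata$n_candidates, "candidate(s) from",
      x$metadata$n_transcripts, "transcripts\n")
  for (cand in x$candidates) {
    cat(sprintf("  %-14s best=%s E=%.2g verdict=%s group=%s\n",
                cand$candidate, cand$best_hit$ref, cand$best_hit$evalue,
                cand$eve_verdict, cand$group_id %||% "-"))
  }
  invisible(x)
}

report_to_json <- function(report) {
  r <- unclass(report)
  r$candidates <- lapply(r$candidates, function(cand) {
    cand$orfs <- as.data.frame(cand$orfs)
    cand
  })
  if (!is.null(r$tissue_means)) {
    r$tissue_means <- as.data.frame(r$tissue_means)
  }
  r
}

# stable hash of a configuration (md5 of its deparsed form)
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(strip_functions(config)), f)
  unname(tools::md5sum(f))
}

strip_functions <- function(x) {
  if (is.function(x)) return("<function>")
  if (is.list(x)) return(lapply(x, strip_functions))
  x
}

# rebuild rich objects (virus models) from a plain YAML list
rebuild_config <- function(config) {
  sim <- config$simulate
  if (!is.null(sim) && !is.null(sim$config$viruses)) {
    sim$config$viruses <- lapply(sim$config$viruses, function(v) {
      if (inherits(v, "virus_model")) v else do.call(virus_model, v)
    })
    abl <- sim$config$abundance_log2
    if (!is.null(abl)) {
      sim$config$abundance_log2 <- lapply(abl, function(m) {
        m <- matrix(unlist(m), ncol = 2, byrow = TRUE,
                    dimnames = list(c("whole_body", "brain", "silk",
                                      "venom"), c("lo", "hi")))
        m
      })
    }
    if (is.data.frame(sim$config$libraries) ||
        is.list(sim$config$libraries)) {
      sim$config$libraries <- as.data.frame(sim$config$libraries)
    }
    config$simulate <- sim
  }
  config
}
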