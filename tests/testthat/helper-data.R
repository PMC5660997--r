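# Shared synthetic datasets, built once per test run.

cached_dataset <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1, eve = TRUE) {
    key <- paste0("s", seed, "_", eve)
    if (is.null(cache[[key]])) {
      cache[[key]] <- build_dataset(default_config(eve = eve), seed = seed)
    }
    cache[[key]]
  }
})

# a small, fast configuration: one polyprotein virus, few host transcripts
small_config <- function(eve = FALSE) {
  cfg <- default_config(eve = eve)
  cfg$viruses <- list(
    virus_model("miniPV", "monopartite_polyprotein", 1500L,
                utr5_len = 200L, au_bias = 0.7, utr3_min = 60L))
  cfg$infections <- list(miniPV = c("ind1", "ind2", "ind3", "ind4"))
  cfg$abundance_log2 <- list(miniPV = matrix(
    c(4, 8, 4, 8, 4, 8, 4, 8), ncol = 2, byrow = TRUE,
    dimnames = list(c("whole_body", "brain", "silk", "venom"),
                    c("lo", "hi"))))
  cfg$n_host_transcripts <- 8L
  cfg$host_genome_length <- 8000L
  cfg
}

truth_segment_ids <- function(ds) {
  unname(unlist(lapply(ds$truth$viruses, function(v)
    vapply(v$segments, `[[`, "", "id"))))
}

lib_reads <- function(ds) {
  setNames(ds$design$libraries$host_mapped_reads,
           ds$design$libraries$library_id)
}
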