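# Shared fixtures: a small but structurally safe simulation (the
# significant-mRNA pool is kept much larger than hub_degree so hubs do
# not accidentally look structurally equivalent to each other), and a
# converter from the external DE dialect to the record shape.

`%||%` <- function(a, b) if (is.null(a)) b else a

test_config <- function(seed = 1L, ...) {
  defaults <- list(
    n_transcripts = 1500L, lncrna_fraction = 0.3, n_significant = 200L,
    n_hub_lncrnas = 3L, hub_degree = 50L, background_degree_max = 12L,
    n_equivalence_blocks = 2L, block_size = 3L,
    block_target_overlap = 0.9, n_gene_sets = 40L,
    planted_enriched_set_overlap = 12L, n_samples = 3000L,
    alteration_base_rate = 0.05, planted_pair_odds_ratio = 16,
    seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# DE table (external column names) -> record shape used by the filters
as_records <- function(tab) {
  data.frame(transcript_id = tab$transcript_id, symbol = tab$symbol,
             biotype = tab$biotype, log2fc = tab$log2FoldChange,
             p = tab$pvalue, q = tab$padj,
             testable = !is.na(tab$pvalue) & !is.na(tab$padj),
             stringsAsFactors = FALSE)
}

# simulate -> filter -> classify -> network, returning the pieces tests
# poke at most often
sim_network <- function(cfg, label = "c1") {
  de <- simulate_de_table(cfg, label)
  it <- simulate_interaction_table(cfg, de)
  sig <- filter_significant(as_records(de$table), filter_spec(0.1, 1.5))
  ct <- suppressMessages(classify_biotypes(sig, label))
  list(de = de, it = it, contrast = ct,
       network = build_network(ct, it$table))
}

random_target_sets <- function(n_sets, universe_size, max_size) {
  universe <- sprintf("G%03d", seq_len(universe_size))
  sets <- lapply(seq_len(n_sets), function(i) {
    sample(universe, sample.int(max_size, 1L))
  })
  names(sets) <- sprintf("L%02d", seq_len(n_sets))
  sets
}
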