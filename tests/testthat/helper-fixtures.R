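# Shared in-code fixtures. Everything is generated; nothing is read from
# disk except files the tests themselves write to tempdir().

tree3 <- function() read_master_tree("((A:1,B:1):1,C:2);")

tree6 <- function() {
  read_master_tree(
    "(((A:0.1,B:0.2):0.15,(C:0.12,D:0.3):0.2):0.1,(E:0.4,F:0.25):0.3);"
  )
}

# A small but non-degenerate simulated bundle for pipeline-level tests.
small_sim <- function(seed = 5, ...) {
  simulate_rer_study(sim_config(
    n_taxa = 16, n_genes = 80, fraction_fast = 0.2, fraction_slow = 0.2,
    fg_clade_size = 5, n_sets = 6, enriched_set_size = 12,
    set_size_range = c(10, 20), seed = seed, ...
  ))
}

ref_consensus <- function(master) consensus_from_tree(master)

write_tmp_lines <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
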