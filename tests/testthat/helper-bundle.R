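# build a complete synthetic input bundle on disk and a matching run_config
make_run_bundle <- function(dir, seed = 201, n_tx = 12, n_hp = 6,
                            n_sites = 6, depth = c(2e5, 2e5)) {
  tx <- generate_transcriptome(n_tx, c(900, 1500), 0.5, seed = seed)
  tx <- plant_hairpins(tx, n_hairpins = n_hp, seed = seed + 1)
  tx <- plant_target_sites(tx, n_sites = n_sites, seed = seed + 2)
  sim <- simulate_libraries(tx, depth = depth, n_background = 80,
                            seed = seed + 3, lib_names = c("g1", "g2"))
  truth <- sim$truth
  write_fasta(setNames(as.vector(tx), names(tx)),
              file.path(dir, "transcripts.fa"))
  write_tag_tsv(sim$libs[[1]], file.path(dir, "g1.tsv"))
  write_tag_tsv(sim$libs[[2]], file.path(dir, "g2.tsv"))
  # references: two random rRNA entries; first two matures declared conserved
  set.seed(seed + 4)
  write_fasta(c(rrna1 = rand_nt(150), rrna2 = rand_nt(120)),
              file.path(dir, "rrna.fa"))
  cons <- truth$hairpins$mature[1:2]
  write_fasta(setNames(chartr("T", "U", cons),
                       paste0("ref-miR100", 1:2)),
              file.path(dir, "mature.fa"))
  dtags <- simulate_degradome(tx, peak_height = 50, bg_fraction = 0.1,
                              seed = seed + 5)
  write.table(data.frame(sequence = names(dtags), count = unname(dtags)),
              file.path(dir, "degradome.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- run_config(
    srna = list(g1 = file.path(dir, "g1.tsv"), g2 = file.path(dir, "g2.tsv")),
    transcripts = file.path(dir, "transcripts.fa"),
    references = list(rRNA = file.path(dir, "rrna.fa"),
                      mature_miRNA = file.path(dir, "mature.fa")),
    degradome = file.path(dir, "degradome.tsv"),
    seed = seed)
  list(cfg = cfg, truth = truth, tx = tx)
}
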