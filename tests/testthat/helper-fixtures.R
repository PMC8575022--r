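# Shared heavyweight fixtures, built once per test run and memoized.
# Problem sizes are scaled for a single desktop CPU: a 165-kb genome of
# 330 bins (30 switching), an 18 healthy + 9 tumor training cohort at
# ~1.6 reads/bin/sample pooled depth, and a two-member ensemble of a
# reduced network.

.fixtures <- new.env(parent = emptyenv())

pipeline_fixture <- function() {
  if (!is.null(.fixtures$pipeline)) return(.fixtures$pipeline)
  ref <- simulate_reference(sim_config(), seed = 11)
  design <- data.frame(
    sample_id = c(sprintf("H%02d", 1:18), sprintf("T%02d", 1:9)),
    class_label = c(rep("healthy_plasma", 18), rep("tumor_tissue", 9)),
    true_r = c(rep(0, 18), rep(1, 9)),
    n_reads = 550L, stringsAsFactors = FALSE)
  dir <- file.path(tempdir(), "dismir_pipeline_fixture")
  simulate_cohort(ref, design, dir, seed = 5)
  manifest <- read_manifest(file.path(dir, "manifest.tsv"))
  regions <- dismir_detect_regions(manifest, file.path(dir, "chrom.sizes"))
  ts <- dismir_training_set(manifest, regions, seed = 3)
  cfg <- dismir_model_config(conv1_filters = 24L, lstm_units = 16L,
                             conv2_filters = 16L, dense_units = c(32L, 8L),
                             epochs = 30L, patience = 6L,
                             batch_size = 64L, seed = 1L)
  ens <- train_dismir_ensemble(ts$train, cfg, n_members = 2L)
  .fixtures$pipeline <- list(ref = ref, dir = dir, manifest = manifest,
                             regions = regions, train = ts$train,
                             reserved = ts$reserved, ensemble = ens)
  .fixtures$pipeline
}

# Estimate r_hat for a fresh test-plasma sample at a given true tumor
# fraction, using the shared pipeline fixture.
fixture_r_hat <- function(true_r, seed, n_reads = 4000L) {
  fx <- pipeline_fixture()
  sm <- simulate_sample(fx$ref, "test_plasma", true_r = true_r,
                        n_reads = n_reads, sample_id = "x", seed = seed)
  dismir_estimate_sample(fx$ensemble, sm$reads, fx$regions)$r_hat
}

# Motif scenario: tumor and healthy reads share the methylation
# distribution; the only class difference is a planted 8-mer in half of
# the tumor reads, so any learned signal is sequence-borne.
motif_fixture <- function() {
  if (!is.null(.fixtures$motif)) return(.fixtures$motif)
  motif <- "TACGTCAT"
  cfg_sim <- sim_config(planted_motif = list(seq = motif, class = "tumor",
                                             prob = 0.5),
                        tumor_meth_switching = c(25.5, 4.5))
  ref <- simulate_reference(cfg_sim, seed = 21)
  tum <- simulate_sample(ref, "tumor_tissue", n_reads = 3000L,
                         sample_id = "T", seed = 1)
  hea <- simulate_sample(ref, "healthy_plasma", n_reads = 3000L,
                         sample_id = "H", seed = 2)
  ec <- encoder_config()
  reads <- rbind(tum$reads, hea$reads)
  trimmed <- trim_reads(reads, ec)
  enc <- encode_reads(trimmed, ec, labels = c(rep(1, 3000), rep(0, 3000)))
  sp <- balance_and_split(enc, seed = 4)
  cfg <- dismir_model_config(conv1_filters = 16L, lstm_units = 12L,
                             conv2_filters = 12L, dense_units = c(24L, 8L),
                             epochs = 10L, patience = 10L,
                             batch_size = 64L, seed = 2L)
  model <- train_dismir(build_dismir_model(cfg), sp$train)
  .fixtures$motif <- list(motif = motif, model = model,
                          train = sp$train, reserved = sp$reserved)
  .fixtures$motif
}
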