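#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study inputs.
#
# The published study analysed (a) 246 aligned mitogenome coding regions
# (10,713 bp) from four Fennoscandian/Arctic areas and (b) 180 skulls with
# 31 3D landmarks from five areas. Those supplementary files are not
# redistributable here, so this driver writes seeded synthetic stand-ins
# with the same statistical structure (discrete mitogenome lineages with
# private mutations; symmetric landmark template with group offsets, sexual
# dimorphism and allometry) into results/sim_inputs/. Drop the real files
# over these paths to run the downstream steps on the actual data.

library(norppa)
seed <- 20260927L
out <- "results/sim_inputs"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## mitogenome arm: four areas on a lineage chain, diversity decreasing
## towards the landlocked lakes
hcfg <- haplo_sim_config(
  L = 2000L, lineage_sep = c(8L, 12L, 20L),
  pop_sizes = c(Arctic = 20L, Baltic = 14L, Ladoga = 12L, Saimaa = 16L),
  private_rate = 1.5, seed = seed)
hsim <- simulate_haplotypes(hcfg)
write_fasta_alignment(hsim$alignment,
                      file.path(out, "alignment.fasta"),
                      file.path(out, "popmap.tsv"))
jsonlite::write_json(
  list(lineage = as.list(hsim$truth$lineage),
       lineage_sep = hcfg$lineage_sep, L = hcfg$L,
       private_rate = hcfg$private_rate, seed = seed),
  file.path(out, "alignment_truth.json"), auto_unbox = TRUE)
cat("alignment:", length(hsim$alignment$ids), "sequences x",
    hsim$alignment$L, "bp ->", file.path(out, "alignment.fasta"), "\n")

## skull arm: five areas, 31 landmarks (12 bilateral pairs + 7 midline)
scfg <- shape_sim_config(
  group_sizes = c(HighArctic = 19L, EastGreenland = 30L, Baltic = 25L,
                  Ladoga = 14L, Saimaa = 12L),
  group_offset_magnitude = 0.02, sex_vector_magnitude = 0.012,
  prop_female = 0.43, prop_unknown = 0.2,
  allometry_magnitude = 0.05, noise_sd = 0.005, seed = seed + 1L)
ssim <- simulate_landmarks(scfg)
write_landmarks_csv(ssim$dataset, file.path(out, "landmarks.csv"))
pr <- ssim$pairing
writeLines(c("left\tright",
             apply(pr$pairs, 1, paste, collapse = "\t"),
             as.character(pr$midline)),
           file.path(out, "pairing.tsv"))
cat("landmarks:", ssim$dataset$n, "specimens x", ssim$dataset$k,
    "landmarks ->", file.path(out, "landmarks.csv"), "\n")
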