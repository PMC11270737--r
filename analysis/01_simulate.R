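#!/usr/bin/env Rscript
# Generate the synthetic study ensembles: the 43-residue regulatory
# construct in its nonphosphorylated (NP), singly phosphorylated at S392
# (SP), fully phosphorylated (FP), and N-terminally pinned (NPlock)
# conditions.  Dihedral dynamics follow a 3-basin Markov model over the
# PPII, alpha and beta regions; phosphorylation conditions share the same
# dynamics so that downstream differences reflect composition, not
# planted conformational shifts.  Writes multi-model PDBs and a manifest
# under scratch/ensembles/.

suppressMessages(library(regensemble))

out_dir <- "scratch/ensembles"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

n_frames <- 300
seed0 <- 2026

model <- markov_dihedral_model(
  centers = rbind(PPII = c(-75, 145), alpha = c(-57, -47),
                  beta = c(-135, 135)),
  transition = matrix(c(0.80, 0.10, 0.10,
                        0.10, 0.80, 0.10,
                        0.10, 0.10, 0.80), 3, 3, byrow = TRUE),
  jitter_sd = 12)

conditions <- list(
  NP = list(top = parse_sequence(reg_sequence(), 351), pin = FALSE),
  NPlock = list(top = parse_sequence(reg_sequence(), 351), pin = TRUE),
  SP = list(top = parse_sequence(reg_sequence(), 351, 392L), pin = FALSE),
  FP = list(top = parse_sequence(reg_sequence(), 351, reg_phosphosites()),
            pin = FALSE))

for (i in seq_along(conditions)) {
  nm <- names(conditions)[i]
  cond <- conditions[[nm]]
  tr <- synthetic_ensemble(cond$top, model, n_frames,
                           seed = seed0 + i, pin_first = cond$pin)
  f <- file.path(out_dir, paste0(nm, ".pdb"))
  write_ensemble(tr, f)
  cat(sprintf("%-6s %d frames, %d atoms, net charge %+d -> %s\n",
              nm, n_frames, n_atoms(tr), formal_net_charge(cond$top), f))
}

manifest <- list(
  n_frames = n_frames, seed = seed0,
  phosphosites = list(SP = 392, FP = reg_phosphosites()),
  basin_centers = list(PPII = c(-75, 145), alpha = c(-57, -47),
                       beta = c(-135, 135)),
  stay_probability = 0.8, jitter_sd = 12)
jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                     auto_unbox = TRUE, pretty = TRUE)
cat("manifest ->", file.path(out_dir, "manifest.json"), "\n")
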