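# Builds the synthetic stand-in fixtures shipped under inst/extdata/.
#
# The original greenhouse study's species trait table, treatment-level CWM
# constraint predictions and per-pot observed abundances were distributed
# only as document attachments and are not publicly deposited. The files
# generated here are synthetic stand-ins: they are constructed once from the
# qualitative facts printed in the study's text (trait contrasts among the
# five grasses, the direction of CWM predictions in sun vs shade, the
# dominance ordering per treatment, and the 33%/31% sun-limestone means) and
# are NOT the original data. Quantitative fit statistics computed from them
# are properties of the stand-ins, not of the study.
#
# Run from the package root: Rscript tools/make_synthetic_fixtures.R

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

# --- species traits: five dominant grasses -------------------------------
# C4 grasses (B. gracilis, M. montana): small seeds, high SRL, late
# flowering; C3 grasses (E. elymoides, F. arizonica, P. fendleriana):
# larger seeds (except P. fendleriana), low SRL, early flowering;
# M. montana has the smallest seed mass.
traits <- data.frame(
  species_id = c("Bouteloua_gracilis", "Muhlenbergia_montana",
                 "Elymus_elymoides", "Festuca_arizonica", "Poa_fendleriana"),
  seed_mass = c(0.30, 0.10, 3.00, 1.10, 0.35),
  srl = c(210, 180, 95, 80, 85),
  flowering_date = c(213, 224, 166, 181, 152)
)
write.csv(traits, "inst/extdata/synthetic_grass_traits.csv",
          row.names = FALSE, quote = FALSE)

# --- treatment-level CWM constraints -------------------------------------
# Higher CWM SRL and later flowering in sun than shade; limestone (pH 6.8)
# shifts further toward the fast/late end than basalt (pH 5.9).
constraints <- data.frame(
  unit_id = c("sun-limestone", "sun-basalt", "shade-limestone", "shade-basalt"),
  seed_mass = c(0.80, 0.60, 1.00, 0.90),
  srl = c(140, 128, 95, 95),
  flowering_date = c(190, 182, 168, 165)
)
write.csv(constraints, "inst/extdata/synthetic_treatment_cwm.csv",
          row.names = FALSE, quote = FALSE)

# --- per-pot observed seedling counts ------------------------------------
# 17/17/16/16 pots per treatment, 12 seeds of each species per pot,
# independent binomial emergence per species. Expected relative abundances
# encode the printed qualitative outcomes: B. gracilis narrowly dominant
# over P. fendleriana in sun-limestone (33% vs 31%), P. fendleriana
# dominant elsewhere, F. arizonica ahead of E. elymoides, M. montana rare.
design <- rbind(
  "sun-limestone"   = c(0.33, 0.10, 0.11, 0.15, 0.31),
  "sun-basalt"      = c(0.27, 0.09, 0.12, 0.20, 0.32),
  "shade-limestone" = c(0.12, 0.08, 0.15, 0.25, 0.40),
  "shade-basalt"    = c(0.13, 0.08, 0.14, 0.23, 0.42)
)
colnames(design) <- traits$species_id
pots_per_cell <- c(17, 17, 16, 16)
seeds <- 12
emergence_scale <- 1.5   # overall emergence ~30% of sown seeds

set.seed(20181130)
rows <- list(); labels <- character(0)
for (t in seq_len(nrow(design))) {
  for (r in seq_len(pots_per_cell[t])) {
    rows[[length(rows) + 1]] <-
      rbinom(ncol(design), seeds, emergence_scale * design[t, ])
    labels <- c(labels, rownames(design)[t])
  }
}
counts <- do.call(rbind, rows)
out <- data.frame(sample_id = sprintf("pot%02d", seq_len(nrow(counts))),
                  treatment = labels, counts)
colnames(out)[-(1:2)] <- colnames(design)
write.csv(out, "inst/extdata/synthetic_pot_counts.csv",
          row.names = FALSE, quote = FALSE)

cat("wrote", nrow(traits), "species,", nrow(constraints), "constraint rows,",
    nrow(out), "pots\n")
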