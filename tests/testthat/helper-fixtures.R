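# Shared builders for small in-code fixtures and paths to the shipped
# synthetic stand-in data (see inst/extdata; these files are synthetic,
# constructed from qualitative descriptions, not original study data).

extdata_path <- function(file) {
  system.file("extdata", file, package = "catspredict", mustWork = TRUE)
}

grass_traits <- function() {
  read_trait_table(extdata_path("synthetic_grass_traits.csv"))
}

treatment_constraints <- function() {
  read_cwm_table(extdata_path("synthetic_treatment_cwm.csv"))
}

pot_counts <- function() {
  read_community_matrix(extdata_path("synthetic_pot_counts.csv"), kind = "count")
}

# minimal valid trait table with chosen values for one trait of interest
toy_traits <- function(values, trait = "seed_mass", ids = NULL) {
  n <- length(values)
  if (is.null(ids)) ids <- paste0("sp", seq_len(n))
  df <- data.frame(species_id = ids,
                   seed_mass = rep(1, n), srl = rep(100, n),
                   flowering_date = rep(180, n))
  df[[trait]] <- values
  trait_table(df)
}

# balanced two-way factors for n = reps per cell * 4
balanced_2x2 <- function(reps) {
  list(a = rep(c("a1", "a1", "a2", "a2"), each = reps),
       b = rep(c("b1", "b2", "b1", "b2"), each = reps))
}
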