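# in-code fixtures shared across test files

toy_table <- function(m = NULL) {
  if (is.null(m)) {
    m <- rbind(s1 = c(spA = 3, spB = 0, spC = 2),
               s2 = c(spA = 1, spB = 2, spC = 0))
  }
  abundance_table(m)
}

toy_meta <- function(n_habitats = 2, sites = 2, times = "T1", reps = 1,
                     strata = "none") {
  grid <- expand.grid(replicate = seq_len(reps), stratum = strata,
                      site = paste0("site", seq_len(sites)),
                      time = times,
                      habitat = paste0("H", seq_len(n_habitats)),
                      stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_%s_%s_%s_r%d", grid$habitat, grid$time,
                            grid$site, grid$stratum, grid$replicate)
  sample_meta(grid)
}

# random abundance table matching a sample_meta
random_table <- function(meta, n_species = 12, lambda = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(nrow(meta) * n_species, lambda),
              nrow = nrow(meta),
              dimnames = list(meta$sample_id, sprintf("sp%02d", seq_len(n_species))))
  # make sure no sample is empty
  m[rowSums(m) == 0, 1] <- 1
  abundance_table(m)
}

# habitat_species_sets built directly from named list of species vectors
make_sets <- function(sets, time = "T1") {
  structure(sets, time = time, class = "habitat_species_sets")
}

# engineered per-habitat species sets with the exact category cardinalities
# of a 4-habitat survey: n_common species in all habitats, per-habitat
# endemics, and per-habitat shifting memberships drawn from explicit combos
engineered_sets <- function(n_common, endemics, combos, prefix = "",
                            time = "T1") {
  habs <- names(endemics)
  common <- sprintf("%scommon%03d", prefix, seq_len(n_common))
  sets <- lapply(habs, function(h) {
    c(common, sprintf("%send_%s_%03d", prefix, h, seq_len(endemics[[h]])))
  })
  names(sets) <- habs
  for (i in seq_along(combos)) {
    cb <- combos[[i]]
    sp <- sprintf("%sshift%03d", prefix, i)
    for (h in cb$habitats) sets[[h]] <- c(sets[[h]], sp)
  }
  make_sets(lapply(sets, unique), time = time)
}

# expand a combo spec list(habitats=..., n=...) into one entry per species
rep_combos <- function(spec) {
  out <- list()
  for (s in spec) {
    for (i in seq_len(s$n)) out[[length(out) + 1L]] <- list(habitats = s$habitats)
  }
  out
}

# rename species ids in a habitat_species_sets according to a map
rename_sets <- function(sets, map) {
  renamed <- lapply(sets, function(s) {
    hit <- s %in% names(map)
    s[hit] <- map[s[hit]]
    unique(s)
  })
  make_sets(renamed, time = attr(sets, "time"))
}
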