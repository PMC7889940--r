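test_that("long reader fills absent pairs with zeros and validates input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,species_id,count",
               "s1,spA,3", "s1,spB,0", "s2,spA,1"), f)
  tab <- read_abundance(f, layout = "long")
  expect_equal(dim(tab), c(2L, 2L))
  expect_equal(unclass(tab)[, c("spA", "spB")],
               rbind(s1 = c(spA = 3, spB = 0), s2 = c(spA = 1, spB = 0)))

  # duplicate pairs are an error, not summed
  writeLines(c("sample_id,species_id,count",
               "s1,spA,3", "s1,spA,1"), f)
  expect_error(read_abundance(f, "long"), "duplicate")

  # negative and fractional counts are named in the error
  writeLines(c("sample_id,species_id,count", "s1,spA,-2"), f)
  expect_error(read_abundance(f, "long"), "negative.*spA")
  writeLines(c("sample_id,species_id,count", "s1,spA,1.5"), f)
  expect_error(read_abundance(f, "long"), "non-integer.*spA")

  writeLines("sample_id,species_id,count", f)
  expect_error(read_abundance(f, "long"), "no species")
})

test_that("write-then-read round-trips exactly in both layouts", {
  meta <- toy_meta(n_habitats = 3, sites = 2)
  tab <- random_table(meta, n_species = 9, seed = 11)
  for (layout in c("long", "wide")) {
    for (ext in c(".csv", ".tsv")) {
      f <- withr::local_tempfile(fileext = ext)
      write_abundance(tab, f, layout)
      back <- read_abundance(f, layout)
      expect_equal(unclass(back)[sample_ids(tab), species_ids(tab)],
                   unclass(tab), ignore_attr = TRUE)
    }
  }
})

test_that("replicate pooling sums counts and conserves the grand total", {
  meta <- toy_meta(n_habitats = 2, sites = 1, reps = 3)
  m <- matrix(0, nrow(meta), 2, dimnames = list(meta$sample_id, c("spX", "spY")))
  m[meta$habitat == "H1", "spX"] <- c(1, 2, 3)
  m[meta$habitat == "H2", "spY"] <- c(4, 0, 1)
  tab <- abundance_table(m)
  out <- pool_replicates(tab, meta)
  expect_equal(nrow(out$table), 2L)
  expect_equal(unclass(out$table)["H1_T1_site1", "spX"], 6)
  expect_equal(sum(out$table), sum(tab))

  # single-replicate groups pass through unchanged
  meta1 <- toy_meta(n_habitats = 2, sites = 2, reps = 1)
  tab1 <- random_table(meta1, seed = 3)
  out1 <- pool_replicates(tab1, meta1)
  expect_equal(sort(rowSums(out1$table)), sort(rowSums(tab1)), ignore_attr = TRUE)
  expect_equal(sum(out1$table), sum(tab1))
})

test_that("pooling conserves totals and never creates species (random fixtures)", {
  for (seed in 1:5) {
    meta <- toy_meta(n_habitats = 3, sites = 2, reps = 3)
    tab <- random_table(meta, n_species = 15, seed = seed)
    out <- pool_replicates(tab, meta)
    expect_equal(sum(out$table), sum(tab))
    expect_setequal(species_ids(out$table), species_ids(tab))
    # a species absent before pooling stays absent
    absent_before <- colSums(unclass(tab)) == 0
    expect_true(all(colSums(unclass(out$table))[absent_before] == 0))
  }
})

test_that("unequal replicate group sizes warn but still pool by summation", {
  meta <- toy_meta(n_habitats = 1, sites = 2, reps = 3)
  meta <- meta[-1, ]                      # one site loses a replicate
  tab <- random_table(sample_meta(as.data.frame(meta)), seed = 5)
  expect_warning(out <- pool_replicates(tab, meta), "unequal")
  expect_equal(sum(out$table), sum(tab))
})

test_that("stratum integration sums strata and matches the set-union oracle", {
  meta <- toy_meta(n_habitats = 1, sites = 1, strata = c("above", "below"))
  m <- rbind(c(4, 0), c(1, 2))
  dimnames(m) <- list(meta$sample_id, c("spA", "spB"))
  tab <- abundance_table(m)
  out <- integrate_strata(tab, meta)
  expect_equal(nrow(out$table), 1L)
  expect_equal(as.vector(unclass(out$table)), c(5, 2))
  expect_true(all(out$meta$stratum == "none"))

  # richness of the integrated site equals the union of strata species sets
  for (seed in 1:4) {
    meta2 <- toy_meta(n_habitats = 2, sites = 2, strata = c("a", "b"))
    tab2 <- random_table(meta2, n_species = 10, lambda = 0.8, seed = seed)
    out2 <- integrate_strata(tab2, meta2)
    m2 <- unclass(tab2)
    md <- as.data.frame(meta2)
    for (i in seq_len(nrow(out2$table))) {
      key <- out2$meta[i, ]
      rows <- md$habitat == key$habitat & md$site == key$site & md$time == key$time
      union_sp <- sort(unique(unlist(lapply(which(rows), function(r) {
        colnames(m2)[m2[r, ] > 0]
      }))))
      got <- sort(colnames(m2)[unclass(out2$table)[i, ] > 0])
      expect_equal(got, union_sp)
    }
    expect_equal(sum(out2$table), sum(tab2))
  }
})

test_that("a site missing an expected stratum integrates with a warning", {
  meta <- toy_meta(n_habitats = 1, sites = 2, strata = c("a", "b"))
  meta <- sample_meta(as.data.frame(meta[-1, ]))   # site1 lacks stratum a
  tab <- random_table(meta, seed = 2)
  expect_warning(out <- integrate_strata(tab, meta), "missing expected strata")
  expect_equal(sum(out$table), sum(tab))
})

test_that("incidence collapse is an idempotent indicator with richness row sums", {
  tab <- toy_table(rbind(s1 = c(spA = 3, spB = 0), s2 = c(spA = 1, spB = 2)))
  inc <- to_incidence(tab)
  expect_equal(as.vector(unclass(inc)), c(1, 1, 0, 1))
  expect_equal(unclass(to_incidence(inc)), unclass(inc))
  meta <- toy_meta(n_habitats = 2, sites = 3)
  rt <- random_table(meta, n_species = 8, lambda = 1.2, seed = 9)
  expect_equal(rowSums(to_incidence(rt)), sample_richness(rt))
})

test_that("validation rejects incomplete metadata joins", {
  meta <- toy_meta(n_habitats = 2, sites = 2)
  tab <- random_table(meta, seed = 1)
  expect_invisible(validate_bundle(tab, meta))
  expect_error(validate_bundle(tab, meta[-1, ]), "without metadata")
  extra <- as.data.frame(meta)
  extra <- rbind(extra, data.frame(sample_id = "ghost", habitat = "H1",
                                   time = "T1", site = "site9",
                                   stratum = "none", replicate = 1))
  expect_error(validate_bundle(tab, sample_meta(extra)), "without samples")
})

test_that("trait tables enforce their declared vocabulary", {
  df <- data.frame(species_id = c("a", "b"), feeding_type = c("Ca", "FS"),
                   life_form = c("BU", "SE"))
  tr <- trait_table(df)
  expect_setequal(attr(tr, "feeding_vocab"), c("Ca", "FS"))
  expect_error(trait_table(df, feeding_vocab = c("Ca")), "outside vocabulary")
  expect_error(trait_table(rbind(df, df)), "duplicate species_id")
})
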