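make_table <- function(m) {
  colnames(m) <- paste0("n", seq_len(ncol(m)))
  project_and_dedup(m)
}

test_that("projection deduplicates and records multiplicity", {
  fp <- rbind(c(I = 0L, A = 1L, B = 0L),
              c(I = 1L, A = 1L, B = 0L),
              c(I = 1L, A = 0L, B = 1L))
  tab <- project_and_dedup(fp, drop_nodes = "I")
  expect_equal(nrow(tab$profiles), 2)
  expect_equal(sum(tab$multiplicity), 3)
  key <- apply(tab$profiles, 1, paste, collapse = "")
  expect_equal(tab$multiplicity[key == "10"], 2L)
  # empty drop set is the identity on rows
  tab2 <- project_and_dedup(fp)
  expect_equal(nrow(tab2$profiles), 3)
  # the bundled model reduces 1384 fixed points to 214 unique profiles
  expect_equal(nrow(bundled_table$profiles), 214)
  expect_equal(sum(bundled_table$multiplicity), nrow(bundled_fp))
})

test_that("non-biological states are exactly the zero and RAGE-only rows", {
  nodes <- intracellular_nodes(bundled_model)
  m <- matrix(0L, 3, length(nodes), dimnames = list(NULL, nodes))
  m[2, "RAGE"] <- 1L
  m[3, "TGFB"] <- 1L
  tab <- project_and_dedup(m)
  parts <- filter_nonbiological(tab)
  expect_equal(nrow(parts$removed$profiles), 2)
  expect_equal(nrow(parts$kept$profiles), 1)
  expect_equal(unname(parts$kept$profiles[1, "TGFB"]), 1L)
  # both non-biological rows exist among the bundled model's attractors
  expect_equal(sum(is_nonbio <- bundled_table$nonbiological), 2)
})

test_that("signature classification follows the marker clauses", {
  sigs <- macpol:::macrophage_signatures("strict")
  nodes <- intracellular_nodes(bundled_model)
  prof <- setNames(rep(0L, length(nodes)), nodes)

  nlc <- prof; nlc[c("TGFB", "HIF1A", "EGF", "RAGE")] <- 1L
  expect_equal(classify_profile(nlc, sigs), "NLC")

  expect_equal(classify_profile(prof, sigs), "M0")

  m1 <- prof; m1[c("IL12", "NFKB", "TNFA", "STAT1")] <- 1L
  expect_equal(classify_profile(m1, sigs), "M1")

  # multi-matching profiles: priority resolves, strict-exclusive sends to M0
  both <- prof
  both[c("IL12", "NFKB", "TNFA", "STAT1",
         "IL10s", "STAT3", "PPARG")] <- 1L
  expect_equal(classify_profile(both, sigs, "priority"), "M2")
  expect_equal(classify_profile(both, sigs, "strict_exclusive"), "M0")
})

test_that("relaxing a signature never shrinks its category (priority policy)", {
  sigs <- macpol:::macrophage_signatures("strict")
  full <- classify_profiles(bundled_table, sigs, "priority")
  relaxed_sigs <- sigs
  relaxed_sigs$M2 <- sigs$M2[-3]  # drop the PPARG clause
  relaxed <- classify_profiles(bundled_table, relaxed_sigs, "priority")
  expect_gte(sum(relaxed$category == "M2"), sum(full$category == "M2"))
})

test_that("category summaries partition the table", {
  s <- summarize_categories(bundled_table)
  expect_equal(sum(s$counts), s$n_profiles)
  expect_equal(sum(s$percent), 100, tolerance = 1e-9)
  expect_equal(s$n_nonbiological, 2)

  single <- make_table(matrix(c(0L, 1L, 1L), 1))
  single <- classify_profiles(single, list(X = list("n2")), "priority")
  s1 <- summarize_categories(single, categories = c("M0", "X"))
  expect_equal(unname(s1$percent["X"]), 100)
  expect_error(summarize_categories(make_table(matrix(1L, 1, 2))),
               "not classified")
})

test_that("averaged category profiles are column means", {
  tab <- make_table(rbind(c(1L, 0L, 1L), c(0L, 1L, 0L)))
  tab$category <- c("A", "A")
  expect_equal(unname(average_profile(tab, "A")), c(0.5, 0.5, 0.5))
  tab$category <- c("A", "B")
  expect_true(all(average_profile(tab, "B") %in% c(0, 1)))
  expect_error(average_profile(tab, "Z"), "no profiles")
  # the NLC signature forces its four markers active in every member
  nlc_mean <- average_profile(bundled_table, "NLC")
  expect_equal(unname(nlc_mean[c("TGFB", "HIF1A", "EGF", "RAGE")]),
               rep(1, 4))
})

test_that("principal-component scores behave like centered PCA", {
  tab <- make_table(rbind(c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L)))
  sc <- pca_coordinates(tab, 1)
  expect_equal(sum(sc[, 1]), 0, tolerance = 1e-12)
  expect_equal(abs(sc[1, 1]), abs(sc[2, 1]), tolerance = 1e-12)

  dup <- make_table(rbind(c(1L, 0L, 1L), c(1L, 0L, 1L), c(0L, 1L, 0L)))
  # deduplication collapses the repeats, so rebuild rows directly
  tab3 <- structure(list(profiles = rbind(c(1L, 0L, 1L), c(1L, 0L, 1L),
                                          c(0L, 1L, 0L)),
                         multiplicity = c(1L, 1L, 1L),
                         category = rep(NA_character_, 3),
                         nonbiological = rep(NA, 3)),
                    class = "profile_table")
  colnames(tab3$profiles) <- paste0("n", 1:3)
  sc3 <- pca_coordinates(tab3, 2)
  expect_equal(sc3[1, ], sc3[2, ], tolerance = 1e-12)

  # total score variance equals total column variance over all components
  sc_all <- pca_coordinates(bundled_table,
                            n_components = ncol(bundled_table$profiles))
  expect_equal(sum(apply(sc_all, 2, stats::var)),
               sum(apply(bundled_table$profiles, 2, stats::var)),
               tolerance = 1e-9)

  degen <- structure(list(profiles = matrix(1L, 3, 2,
                                            dimnames = list(NULL, c("a", "b"))),
                          multiplicity = rep(1L, 3),
                          category = rep(NA_character_, 3),
                          nonbiological = rep(NA, 3)),
                     class = "profile_table")
  expect_error(pca_coordinates(degen), "degenerate")
})
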