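demo_groups <- function() {
  species_groups(focal = "sc",
                 sister = c("sf", "sg"),
                 distant = c("ss", "bm"),
                 other = "hb")
}

write_groups_file <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

test_that("groups parsing handles members, separators and malformed input", {
  cl <- parse_groups(write_groups_file("c1: sc|p1 ss|p9"))
  expect_equal(nrow(cl$members), 2)
  expect_equal(cl$members$species_id, c("sc", "ss"))
  expect_equal(cl$members$protein_id, c("p1", "p9"))
  expect_equal(nrow(parse_groups(write_groups_file(character()))$members), 0)
  expect_error(parse_groups(write_groups_file("no separator here")),
               "malformed")
  expect_error(
    parse_groups(write_groups_file(c("c1: sc|p1", "c2: sc|p1 sf|p2"))),
    "more than one cluster.*p1")
  expect_error(parse_groups(write_groups_file("c1: zz|p1"),
                            species = c("sc", "sf")),
               "unknown species")
})

test_that("singleton augmentation covers every venom protein exactly once", {
  cl <- parse_groups(write_groups_file("c1: sc|p1 sf|p2"))
  aug <- augment_singletons(cl, c("p1", "p3", "p4"), "sc")
  expect_equal(nrow(aug$members), 4)
  expect_setequal(aug$members$protein_id[aug$members$species_id == "sc"],
                  c("p1", "p3", "p4"))
  # already-covered input is returned unchanged
  expect_identical(augment_singletons(cl, "p1", "sc"), cl)
  # counting oracle across random fixtures
  withr::with_seed(21, {
    for (i in 1:10) {
      n_clustered <- sample(0:10, 1); n_free <- sample(0:10, 1)
      if (n_clustered + n_free == 0) next
      venom <- sprintf("v%02d", seq_len(n_clustered + n_free))
      lines <- if (n_clustered > 0)
        sprintf("c%d: sc|%s", seq_len(n_clustered), venom[seq_len(n_clustered)])
      else "bg1: sf|x1"
      aug <- augment_singletons(parse_groups(write_groups_file(lines)),
                                venom, "sc")
      got <- sum(aug$members$species_id == "sc" &
                   aug$members$protein_id %in% venom)
      expect_equal(got, length(venom))
    }
  })
})

test_that("categorisation applies distant > sister > specific precedence", {
  gr <- demo_groups()
  lines <- c("c1: sc|v1 ss|x1 sf|y1",  # distant wins over sister
             "c2: sc|v2 sf|y2",        # sister
             "c3: sc|v3",              # singleton -> specific
             "c4: sc|v4 hb|z1")        # outgroup member leaves it specific
  cl <- parse_groups(write_groups_file(lines))
  cats <- categorize_venom(cl, c("v1", "v2", "v3", "v4"), gr)
  expect_equal(as.character(cats$category[match(paste0("v", 1:4),
                                                cats$protein_id)]),
               c("distant_conserved", "sister_conserved",
                 "focal_specific", "focal_specific"))
  expect_error(categorize_venom(cl, c("v1", "v9"), gr), "v9")
})

test_that("categorisation is invariant to line and member order", {
  gr <- demo_groups()
  lines <- c("c1: sc|v1 ss|x1 sf|y1", "c2: sc|v2 sf|y2", "c3: sc|v3")
  cl1 <- parse_groups(write_groups_file(lines))
  cl2 <- parse_groups(write_groups_file(
    c("c3: sc|v3", "c1: sf|y1 sc|v1 ss|x1", "c2: sf|y2 sc|v2")))
  v <- c("v1", "v2", "v3")
  expect_identical(categorize_venom(cl1, v, gr)$category,
                   categorize_venom(cl2, v, gr)$category)
})

test_that("with no distant species configured nothing is distant-conserved", {
  gr <- species_groups("sc", sister = c("sf", "sg", "ss", "bm"),
                       distant = character())
  cl <- parse_groups(write_groups_file(c("c1: sc|v1 ss|x1", "c2: sc|v2")))
  cats <- categorize_venom(cl, c("v1", "v2"), gr)
  expect_false(any(cats$category == "distant_conserved"))
})

test_that("species group configuration rejects overlaps", {
  expect_error(species_groups("sc", c("sf", "ss"), c("ss")), "disjoint")
  expect_error(species_groups("sc", c("sc"), c("ss")), "focal")
})

test_that("category summary tallies counts and percentages", {
  gr <- demo_groups()
  # a 43 / 57 split of 100 venom proteins, mirroring the headline proportions
  lines <- c(sprintf("d%02d: sc|v%03d ss|x%03d", 1:43, 1:43, 1:43),
             sprintf("s%02d: sc|v%03d", 1:57, 44:100))
  cl <- parse_groups(write_groups_file(lines))
  cats <- categorize_venom(cl, sprintf("v%03d", 1:100), gr)
  s <- category_summary(cats)
  expect_equal(s$n, c(43L, 0L, 57L))
  expect_equal(s$pct, c(43, 0, 57))
  expect_equal(sum(s$n), 100)
  # randomized maps equal a brute-force tally
  withr::with_seed(8, {
    for (i in 1:5) {
      fake <- data.frame(
        protein_id = sprintf("p%d", 1:50),
        cluster_id = sprintf("c%d", 1:50),
        category = factor(sample(venomkit:::conservation_levels(), 50, TRUE),
                          levels = venomkit:::conservation_levels()))
      s <- category_summary(fake)
      expect_equal(s$n, as.integer(table(fake$category)))
      expect_equal(sum(s$fraction), 1, tolerance = 1e-12)
    }
  })
})

test_that("molar breakdown sums fractions per category and reports the pooled slice", {
  cats <- data.frame(protein_id = c("a", "b", "c"),
                     cluster_id = c("c1", "c2", "c3"),
                     category = factor(c("distant_conserved",
                                         "sister_conserved",
                                         "focal_specific"),
                                       levels = venomkit:::conservation_levels()))
  emp <- molar_fractions(data.frame(protein_id = c("a", "b", "c"),
                                    empai = c(1, 3, 6)))
  br <- venom_molar_breakdown(cats, emp)
  expect_equal(br$molar_pct, c(10, 30, 60))
  expect_equal(sum(br$molar_pct), 100, tolerance = 1e-6)
  expect_equal(attr(br, "genus_specific_pct"), 90)
  emp_bad <- molar_fractions(data.frame(protein_id = c("a", "zz"),
                                        empai = c(1, 1)))
  expect_error(venom_molar_breakdown(cats, emp_bad), "zz")
})

test_that("a design planting 85% of molar abundance on specific proteins is recovered", {
  # 40 specific proteins carry 85% of the planted abundance, 60 conserved
  # proteins share the remaining 15%; detection-driven emPAI should put the
  # specific slice near 85%
  withr::with_seed(31, {
    cats <- data.frame(
      protein_id = sprintf("p%03d", 1:100),
      cluster_id = sprintf("c%03d", 1:100),
      category = factor(rep(c("distant_conserved", "focal_specific"),
                            c(60, 40)),
                        levels = venomkit:::conservation_levels()))
    emp <- data.frame(protein_id = cats$protein_id,
                      empai = c(runif(60, 0.5, 1), runif(40, 0.5, 1)))
    emp$empai <- emp$empai / ave(emp$empai, cats$category, FUN = sum) *
      rep(c(15, 85), c(60, 40))
  })
  br <- venom_molar_breakdown(cats, molar_fractions(emp))
  expect_equal(br$molar_pct[br$category == "focal_specific"], 85,
               tolerance = 1e-6)
})

test_that("cluster ranking orders by venom fraction with deterministic ties", {
  gr <- demo_groups()
  cl <- parse_groups(write_groups_file(
    c("c1: sc|v1 sc|v2 ss|x1", "c2: sc|v3 sf|y1", "c3: sc|v4")))
  cats <- categorize_venom(cl, paste0("v", 1:4), gr)
  emp <- molar_fractions(data.frame(protein_id = paste0("v", 1:4),
                                    empai = c(2, 3, 3, 2)))
  tab <- rank_clusters(cl, cats, emp)
  expect_equal(tab$cluster_id[tab$rank == 1], "c1")  # 0.5 of the venom
  expect_equal(tab$fraction_of_venom[order(tab$cluster_id)],
               c(0.5, 0.3, 0.2))
  expect_equal(sum(tab$fraction_of_venom), 1, tolerance = 1e-9)
  expect_equal(tab$sc[order(tab$cluster_id)], c(2, 1, 1))
  # single cluster: rank 1, fraction 1
  cl1 <- parse_groups(write_groups_file("c1: sc|v1"))
  cats1 <- categorize_venom(cl1, "v1", gr)
  tab1 <- rank_clusters(cl1, cats1,
                        molar_fractions(data.frame(protein_id = "v1",
                                                   empai = 5)))
  expect_equal(tab1$rank, 1L)
  expect_equal(tab1$fraction_of_venom, 1)
})
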