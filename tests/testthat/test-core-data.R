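test_that("trait CSV round-trips and violations are rejected with row context", {
  tr <- data.frame(species_id = c("sp1", "sp2", "sp3"),
                   site_id = "a", la = c(100, 2000, 350),
                   sla = c(12, 20, 33), ldmc = c(40, 25, 18))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(tr, f, row.names = FALSE)
  got <- read_traits(f)
  expect_equal(got[names(tr)], tr, ignore_attr = TRUE)

  bad <- tr; bad$ldmc[2] <- 120
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_traits(f), "row\\(s\\) 2")

  dup <- rbind(tr, tr[1, ])
  write.csv(dup, f, row.names = FALSE)
  expect_error(read_traits(f), "sp1 @ a")

  nohdr <- tr; names(nohdr)[3] <- "leaf_area"
  write.csv(nohdr, f, row.names = FALSE)
  expect_error(read_traits(f), "missing column")

  nonnum <- tr; nonnum$sla <- as.character(nonnum$sla); nonnum$sla[3] <- "abc"
  write.csv(nonnum, f, row.names = FALSE)
  expect_error(read_traits(f), "not numeric at row\\(s\\) 3")
})

test_that("leaf measurements aggregate to SLA/LDMC in the stated order", {
  m <- data.frame(species_id = "sp1", site_id = "a", individual_id = 1,
                  lfw = 100, ldw = 30, la = 600)
  out <- traits_from_leaves(m)
  expect_equal(out$sla, 20)
  expect_equal(out$ldmc, 30)
  expect_equal(out$la, 600)

  # two leaves with sla 10 and 30 on one individual average to 20
  m2 <- data.frame(species_id = "sp1", site_id = "a", individual_id = 1,
                   lfw = c(100, 100), ldw = c(30, 10), la = c(300, 300))
  expect_equal(traits_from_leaves(m2)$sla, mean(c(10, 30)))

  # leaves->individual->species: unbalanced leaf counts distinguish orders
  m3 <- data.frame(species_id = "sp1", site_id = "a",
                   individual_id = c(1, 1, 2),
                   lfw = c(100, 100, 100), ldw = c(10, 30, 40),
                   la = c(400, 400, 400))
  expect_equal(traits_from_leaves(m3)$ldmc, mean(c(mean(c(10, 30)), 40)))
  expect_equal(traits_from_leaves(m3, aggregate = "pool_leaves")$ldmc,
               mean(c(10, 30, 40)))
  expect_equal(traits_from_leaves(m3)$n_individuals, 2)

  # ldw = lfw passes here but trips the trait invariant downstream
  m4 <- data.frame(species_id = "sp1", site_id = "a",
                   lfw = 50, ldw = 50, la = 500)
  out4 <- traits_from_leaves(m4)
  expect_equal(out4$ldmc, 100)
  expect_error(validate_traits(out4), "ldmc")

  expect_error(traits_from_leaves(
    data.frame(species_id = "x", site_id = "a", lfw = 10, ldw = 11, la = 5)),
    "ldw <= lfw")
})

test_that("trait derivation is scale-consistent", {
  m <- data.frame(species_id = "sp1", site_id = "a", individual_id = 1,
                  lfw = 80, ldw = 24, la = 480)
  base <- traits_from_leaves(m)
  mw <- m; mw$lfw <- m$lfw * 3.7; mw$ldw <- m$ldw * 3.7
  expect_equal(traits_from_leaves(mw)$ldmc, base$ldmc)
  ma <- m; ma$la <- m$la * 3.7; ma$ldw <- m$ldw * 3.7; ma$lfw <- m$lfw * 5
  expect_equal(traits_from_leaves(ma)$sla, base$sla)
})

test_that("census reading applies the inclusive DBH >= 1 cm rule", {
  f <- withr::local_tempfile(fileext = ".csv")
  stems <- data.frame(plot_id = "p1", site_id = "a", species_id = "sp1",
                      dbh_cm = c(0.5, 1.0, 2.3))
  write.csv(stems, f, row.names = FALSE)
  expect_equal(read_census(f)$stems, 2L)
  expect_equal(read_census(f, dbh_filter = FALSE)$stems, 3L)

  agg <- small_census()
  write.csv(agg, f, row.names = FALSE)
  expect_equal(read_census(f, dbh_filter = TRUE)$stems,
               read_census(f, dbh_filter = FALSE)$stems)

  writeLines("plot_id,site_id,species_id,stems", f)
  expect_error(read_census(f), "empty")

  two_sites <- agg; two_sites$site_id[2] <- "b"
  write.csv(two_sites, f, row.names = FALSE)
  expect_error(read_census(f), "more than one site_id")
})

test_that("community matrix pivot conserves stems and inverts", {
  cen <- small_census()
  m <- community_matrix(cen)
  expect_equal(dim(m), c(3L, 4L))
  expect_equal(colnames(m), sort(unique(cen$species_id)))
  expect_equal(unname(rowSums(m)),
               as.numeric(tapply(cen$stems, cen$plot_id, sum)))
  expect_equal(m["p1", "sp3"], 6L)
  expect_equal(m["p2", "sp4"], 0L)

  long <- matrix_to_long(m)
  expect_equal(long[order(long$plot_id, long$species_id), ],
               cen[order(cen$plot_id, cen$species_id),
                   c("plot_id", "species_id", "stems")],
               ignore_attr = TRUE)

  single <- cen[cen$plot_id == "p3", ]
  m1 <- community_matrix(single)
  expect_equal(dim(m1), c(1L, 1L))
  expect_equal(sum(m1), sum(single$stems))
})

test_that("pivot conservation holds over random censuses", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    cen <- data.frame(
      plot_id = sample(sprintf("p%d", 1:6), n, replace = TRUE),
      species_id = sample(sprintf("sp%d", 1:12), n, replace = TRUE),
      stems = sample(1:9, n, replace = TRUE))
    cen$site_id <- "a"
    cen <- aggregate(stems ~ plot_id + site_id + species_id, cen, sum)
    expect_equal(sum(community_matrix(cen)), sum(cen$stems))
  }
})
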