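test_that("within/between percentages reproduce the country-level arithmetic", {
  # geriatric population estimates per country and full country totals
  tab <- data.frame(
    geography = c("England", "Northern Ireland", "Scotland", "Wales"),
    category = "geriatric",
    estimate = c(1666510.22, 45087.37, 169554.96, 119948.62))
  totals <- c(England = 10486868, `Northern Ireland` = 266367,
              Scotland = 1155625, Wales = 733714)
  out <- within_between_pct(tab, totals)
  expect_equal(out$within_pct[out$geography == "England"], 15.9)
  expect_equal(out$between_pct[out$geography == "England"], 83.3)
  expect_equal(out$within_pct, c(15.9, 16.9, 14.7, 16.3))
  expect_equal(out$between_pct, c(83.3, 2.3, 8.5, 6.0))
  # between percentages sum to 100 across geographies
  expect_lt(abs(sum(out$between_pct) - 100), 0.15)
  expect_error(within_between_pct(tab, totals[1:2]), "mismatch")
})

test_that("single-geography partitions put 100 percent between", {
  tab <- data.frame(geography = "England",
                    category = c("a", "b"), estimate = c(30, 70))
  out <- within_between_pct(tab)
  expect_equal(out$between_pct, c(100, 100))
  expect_equal(sum(out$within_pct), 100)
})

test_that("posterior partitioning is additive and label-checked", {
  summ <- data.frame(group = c("England", "Scotland"), mean = c(1000, 500))
  demo <- data.frame(geography = rep(c("England", "Scotland"), each = 2),
                     category = rep(c("puppy", "senior"), 2),
                     count = c(10, 90, 40, 60),
                     proportion = c(0.1, 0.9, 0.4, 0.6))
  out <- partition_estimates(summ, demo)
  expect_equal(sum(out$estimate[out$geography == "England"]), 1000)
  expect_equal(sum(out$estimate[out$geography == "Scotland"]), 500)
  # within percentages sum to 100 per geography
  for (g in c("England", "Scotland"))
    expect_lt(abs(sum(out$within_pct[out$geography == g]) - 100), 0.1)
  demo_bad <- demo; demo_bad$geography[1] <- "Atlantis"
  expect_error(partition_estimates(summ, demo_bad), "Atlantis")
})

test_that("demographic tables report proportions that sum to one", {
  w <- small_world()
  demo <- demographic_table(w$clean, "age_group")
  sums <- tapply(demo$proportion, demo$geography, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  dm <- demographic_table(w$clean, "body_size")
  expect_false("unclassified" %in% dm$category)
  expect_gt(attr(dm, "metadata")$excluded_unclassified, 0)
})

test_that("per-capita densities divide draws by people and flag outliers", {
  geo <- toy_geo()
  h <- geo$human_population
  # all draws equal to the human population: density exactly 1
  fd <- fake_draws(list(matrix(h, 5, 4, byrow = TRUE),
                        matrix(h, 5, 4, byrow = TRUE)), geo$area)
  pc <- per_capita(fd, geo)
  expect_equal(pc$mean, rep(1, 4))
  expect_false(any(pc$outlier))
  expect_true(all(pc$lower <= pc$mean & pc$mean <= pc$upper))
  # a constructed outlier at 2.9 dogs per person trips the flag
  m <- matrix(h, 5, 4, byrow = TRUE); m[, 2] <- h[2] * 2.9
  fd2 <- fake_draws(list(m, m), geo$area)
  expect_equal(per_capita(fd2, geo)$outlier, c(FALSE, TRUE, FALSE, FALSE))
  geo$human_population[1] <- 0
  expect_error(per_capita(fd, geo), "positive")
})

test_that("breed rankings order by count with alphabetical ties", {
  recs <- data.frame(
    breed_canonical = c(rep("Labrador Retriever", 5), rep("Pug", 3),
                        rep("Beagle", 3), rep("Mix Breed", 2),
                        "Border Collie cross/type"),
    lineage = c(rep("purebred", 11), rep("mixbreed", 2), "crossbred"),
    country = "England")
  top <- rank_breeds(recs, "purebred", top_k = 10)
  expect_equal(top$breed, c("Labrador Retriever", "Beagle", "Pug"))
  expect_equal(top$count, c(5, 3, 3))
  expect_equal(top$pct, c(45.5, 27.3, 27.3))
  expect_lt(abs(sum(top$pct) - 100), 0.15)
  cross <- rank_breeds(recs, "crossbred", top_k = 5)
  expect_equal(cross$breed, "Border Collie cross/type")
  expect_equal(cross$pct, 100)
  cross_mix <- rank_breeds(recs, "crossbred", top_k = 5, include_mix = TRUE)
  expect_equal(cross_mix$breed[1], "Mix Breed")
  expect_error(rank_breeds(recs, "purebred", top_k = 0), "top_k")
})

test_that("lineage ratios and replacement arithmetic match printed values", {
  r <- pure_cross_ratio(8997180, 1489689)
  expect_equal(r$ratio, 6.04)
  expect_equal(r$label, "6.04:1")
  expect_true(pure_cross_ratio(10, 0)$infinite)
  # 12.64 million dogs at median lifespans of 12.5 and 12.0 years
  expect_equal(replacement_rate(12.64e6, 12.5), 1.01)
  expect_equal(replacement_rate(12.64e6, 12.0), 1.05)
  expect_error(replacement_rate(1e6, 0), "lifespan")
})

test_that("ratios_and_replacement assembles per-geography reports", {
  recs <- data.frame(
    lineage = c(rep("purebred", 80), rep("crossbred", 15), rep("mixbreed", 5)),
    sex = rep(c("M", "F"), 50),
    country = "England")
  summ <- data.frame(group = "England", mean = 1e6)
  out <- ratios_and_replacement(summ, recs, c(12, 12.5))
  expect_equal(out$lineage_ratios$ratio, 4)
  expect_equal(out$sex_ratios$ratio, 1)
  expect_equal(out$replacement$replacement_millions,
               replacement_rate(1e6, c(12, 12.5)))
})

test_that("reference correlation follows the textbook formula", {
  est <- data.frame(area = letters[1:5], value = c(3, 7, 1, 9, 4))
  expect_equal(correlate_reference(est, est)$r, 1)
  neg <- est; neg$value <- -(est$value - mean(est$value))
  expect_equal(correlate_reference(est, neg)$r, -1)
  ref <- data.frame(area = letters[1:5], value = c(2, 6, 3, 10, 3))
  out <- correlate_reference(est, ref)
  x <- est$value; y <- ref$value
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, hand, tolerance = 1e-12)
  expect_equal(out$df, 3)
  expect_error(correlate_reference(est[1:2, ], ref), "3 shared")
})
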