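test_that("percent inhibition anchors and hand-computed value", {
  expect_equal(inhibition_percent(1.00, 1.00, 0.10), 0)
  expect_equal(inhibition_percent(0.10, 1.00, 0.10), 100)
  # (1 - 0.45/0.90) * 100
  expect_equal(inhibition_percent(0.55, 1.00, 0.10), 50)
  expect_error(inhibition_percent(0.5, 0.1, 0.2), "control OD")
})

test_that("inhibition is invariant under rescaling all ODs", {
  set.seed(31)
  for (i in 1:10) {
    s <- runif(1, 0.1, 1); ctrl <- runif(1, 1, 2); bl <- runif(1, 0, 0.09)
    k <- runif(1, 0.1, 10)
    expect_equal(inhibition_percent(k * s, k * ctrl, k * bl),
                 inhibition_percent(s, ctrl, bl))
  }
})

test_that("replicate summaries report mean and SEM", {
  r <- summarize_inhibition(c(50, 50, 50), "x", "BuChE")
  expect_equal(r$mean_inhibition, 50)
  expect_equal(r$sem, 0)
  r <- summarize_inhibition(c(40, 50, 60))
  expect_equal(r$mean_inhibition, 50)
  expect_equal(r$sem, 10 / sqrt(3), tolerance = 1e-9) # sd 10, n 3
  expect_equal(r$n, 3L)
  expect_error(summarize_inhibition(c(50, 60)), "insufficient replicates")
})

test_that("ANOVA/LSD: identical groups give no significant pairs", {
  g <- list(a = c(49, 50, 51), b = c(49, 50, 51))
  res <- anova_lsd(g)
  expect_equal(res$anova$p, 1, tolerance = 1e-9)
  expect_false(any(res$pairs$significant))
})

test_that("ANOVA/LSD: separated groups are significant, degenerate errors", {
  g <- list(low = c(2, 5, 3), high = c(95, 99, 100))
  res <- anova_lsd(g)
  expect_true(all(res$pairs$significant))
  expect_lt(res$anova$p, 1e-6)
  expect_error(anova_lsd(list(a = c(1, 1, 1), b = c(2, 2, 2))), "degenerate")
  expect_error(anova_lsd(list(a = c(1, 2), b = c(1, 2, 3))), "n >= 3")
})

test_that("LSD flags agree with a permutation oracle on seeded data", {
  # two equal groups and one separated; agreement of the significance flag
  # with a label-permutation test, aggregated over seeds and pairs
  perm_p <- function(x, y, n_perm = 1000L) {
    obs <- abs(mean(x) - mean(y))
    pooled <- c(x, y)
    n <- length(x)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample(length(pooled), n)
      if (abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs) hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  }
  agree <- 0L; total <- 0L
  for (seed in 1:30) {
    set.seed(seed)
    g <- list(a = rnorm(6, 50, 3), b = rnorm(6, 50, 3), c = rnorm(6, 80, 3))
    res <- anova_lsd(g)
    for (k in seq_len(nrow(res$pairs))) {
      p <- res$pairs[k, ]
      flag_perm <- perm_p(g[[p$a]], g[[p$b]]) < 0.05
      total <- total + 1L
      if (flag_perm == p$significant) agree <- agree + 1L
    }
  }
  expect_gte(agree / total, 0.95)
})

test_that("ranking the extract screen selects the ultrasonic EtOAc extract", {
  tab <- read_screen_table(system.file("extdata", "extract_screen.tsv",
                                       package = "saponinscreen"))
  ext <- tab[tab$role == "extract", ]
  # no extract shows AChE inhibition at all
  expect_true(all(is.na(ext$mean_inhibition[ext$enzyme == "AChE"])))
  bu <- ext[ext$enzyme == "BuChE", ]
  bu$agent_id <- paste(bu$agent_id, bu$technique, sep = "/")
  rk <- rank_agents(bu)
  expect_equal(rk$agent_id[1], "Ethyl acetate/ultrasonic")
  expect_equal(rk$mean_inhibition[1], 44.1)
  # not-detected rows are excluded, not ranked as zero
  expect_false(any(grepl("^Water/", rk$agent_id)))
})

test_that("ranking the compound screen selects compound 3 for BuChE", {
  tab <- read_screen_table(system.file("extdata", "compound_screen.tsv",
                                       package = "saponinscreen"))
  cmp <- tab[tab$role == "compound" & tab$enzyme == "BuChE", ]
  rk <- rank_agents(cmp)
  expect_equal(rk$agent_id[1], "3")
  expect_equal(rk$mean_inhibition[1], 75.8)
})

test_that("ranking contracts: single agent, ties, mixed enzymes, empty", {
  one <- data.frame(agent_id = "a", enzyme = "BuChE", mean_inhibition = 10,
                    sem = 1)
  expect_equal(rank_agents(one)$rank, 1L)
  tie <- data.frame(agent_id = c("b", "a"), enzyme = "BuChE",
                    mean_inhibition = c(10, 10), sem = c(2, 1))
  expect_equal(rank_agents(tie)$agent_id, c("a", "b")) # SEM breaks the tie
  mixed <- data.frame(agent_id = c("a", "b"), enzyme = c("AChE", "BuChE"),
                      mean_inhibition = c(1, 2), sem = c(0, 0))
  expect_error(rank_agents(mixed), "same enzyme")
  expect_error(rank_agents(one[0, ]), "no results")
})

test_that("plate grids round-trip through TSV and yield well inhibition", {
  p <- simulate_plate(50, od_sigma = 0, n = 4, seed = 5)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_plate(p, f1, f2)
  p2 <- read_plate(f1, f2, agent_id = p$agent_id, enzyme = p$enzyme)
  expect_equal(unname(p2$readings), unname(p$readings), tolerance = 1e-6)
  expect_equal(plate_inhibition(p2), rep(50, 4))
})
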