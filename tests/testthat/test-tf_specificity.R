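test_that("row z-normalization uses the sample sd and centers rows", {
  m <- rbind(a = c(1, 3), b = c(4, 4), c = rnorm(2) + 5)
  colnames(m) <- c("x", "y")
  z <- znormalize_rows(m)
  expect_equal(unname(z["a", ]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(z["b", ]), c(0, 0))
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_error(znormalize_rows(m[, 1, drop = FALSE]), ">= 2")
})

test_that("active TF selection equals the brute-force double criterion", {
  set.seed(61)
  m <- matrix(rlnorm(20 * 8), 20, 8,
              dimnames = list(sprintf("TF%02d", 1:20), paste0("c", 1:8)))
  # one constant, clearly top row: always selected (CV = 0)
  m["TF01", ] <- max(m) * 2
  got <- find_active_tfs(m, top_fraction = 0.2, cv_max = 0.5)
  means <- rowMeans(m)
  cvs <- apply(m, 1, sd) / means
  top <- names(sort(means, decreasing = TRUE))[1:ceiling(0.2 * 20)]
  oracle <- sort(top[cvs[top] < 0.5])
  expect_identical(got, oracle)
  expect_true("TF01" %in% got)

  # highest-mean TF with high CV is rejected by the CV gate
  m2 <- m
  m2["TF02", ] <- c(max(m) * 16, rep(0.01, 7))
  expect_gt(rowMeans(m2)["TF02"], max(rowMeans(m2)[-2]))
  expect_false("TF02" %in% find_active_tfs(m2, 0.2, 0.5))
})

test_that("log-normal scores pass the Shapiro-Wilk gate at high rate", {
  set.seed(71)
  groups <- list(g1 = paste0("a", 1:20), g2 = paste0("b", 1:20))
  fracs <- replicate(50, {
    m <- matrix(rlnorm(30 * 40, sdlog = 0.6), 30, 40,
                dimnames = list(paste0("TF", 1:30),
                                c(groups$g1, groups$g2)))
    lognormality_fraction(m, groups)
  })
  # a TF passes when neither of two independent tests rejects at
  # alpha = 0.05, so the null pass fraction is (1 - 0.05)^2
  expect_equal(mean(fracs), 0.95^2, tolerance = 0.03)
  expect_gte(mean(fracs), 0.85)

  # heavy-tailed contamination is rejected more often than clean rows
  set.seed(72)
  clean <- replicate(20, {
    m <- matrix(rlnorm(20 * 40, sdlog = 0.5), 20, 40,
                dimnames = list(paste0("TF", 1:20),
                                c(groups$g1, groups$g2)))
    lognormality_fraction(m, groups)
  })
  dirty <- replicate(20, {
    m <- matrix(rlnorm(20 * 40, sdlog = 0.5) *
                  exp(pmax(pmin(rt(20 * 40, df = 2), 10), -10)), 20, 40,
                dimnames = list(paste0("TF", 1:20),
                                c(groups$g1, groups$g2)))
    lognormality_fraction(m, groups)
  })
  expect_gt(mean(clean), mean(dirty))

  # identical values make the test undefined and count as failure
  m <- matrix(1, 2, 40, dimnames = list(c("a", "b"),
                                        c(groups$g1, groups$g2)))
  expect_equal(lognormality_fraction(m, groups), 0)
})

test_that("specificity tests agree with closed-form references", {
  set.seed(81)
  for (rep in 1:200) {
    nt <- sample(3:6, 1)
    nb <- sample(3:10, 1)
    m <- matrix(rlnorm(nt + nb), 1, nt + nb,
                dimnames = list("TF1", paste0("c", seq_len(nt + nb))))
    des <- group_design(paste0("c", 1:nt),
                        paste0("c", nt + seq_len(nb)))
    call <- specific_tfs(m, des, p_cut = 0.05, lfc_cut = NULL)
    xt <- log10(m[1, des$target])
    xb <- log10(m[1, des$background])
    # Welch statistic and Welch-Satterthwaite df, written out directly
    se2t <- var(xt) / nt
    se2b <- var(xb) / nb
    tstat <- (mean(xt) - mean(xb)) / sqrt(se2t + se2b)
    df <- (se2t + se2b)^2 /
      (se2t^2 / (nt - 1) + se2b^2 / (nb - 1))
    p_ref <- 2 * pt(-abs(tstat), df)
    expect_equal(call$p_value, p_ref, tolerance = 1e-10)
    expect_equal(call$log2_fc,
                 log2(mean(m[1, des$target]) /
                        mean(m[1, des$background])),
                 tolerance = 1e-12)
  }
})

test_that("small target groups fall back to the one-sample t-test", {
  set.seed(82)
  m <- matrix(rlnorm(2 * 10), 2, 10,
              dimnames = list(c("TF1", "TF2"), paste0("c", 1:10)))
  des <- group_design(c("c1", "c2"), paste0("c", 3:10))
  calls <- specific_tfs(m, des, p_cut = 0.1, lfc_cut = NULL)
  expect_true(all(calls$test == "one_sample"))
  xb <- log10(m[1, des$background])
  mu <- mean(log10(m[1, des$target]))
  tstat <- (mean(xb) - mu) / (sd(xb) / sqrt(8))
  expect_equal(calls$p_value[1], 2 * pt(-abs(tstat), 7),
               tolerance = 1e-10)
})

test_that("pass rate under the null matches the p cutoff", {
  set.seed(91)
  n_tf <- 1000
  m <- matrix(rlnorm(n_tf * 20, sdlog = 0.5), n_tf, 20,
              dimnames = list(paste0("TF", 1:n_tf), paste0("c", 1:20)))
  des <- group_design(paste0("c", 1:4), paste0("c", 5:20))
  for (p_cut in c(0.05, 0.1)) {
    calls <- specific_tfs(m, des, p_cut = p_cut, lfc_cut = NULL)
    rate <- mean(calls$pass)
    se <- sqrt(p_cut * (1 - p_cut) / n_tf)
    expect_lt(abs(rate - p_cut), 3 * se)
  }
})

test_that("calls are invariant to rescaling the score matrix", {
  set.seed(92)
  m <- matrix(rlnorm(50 * 12), 50, 12,
              dimnames = list(paste0("TF", 1:50), paste0("c", 1:12)))
  des <- group_design(paste0("c", 1:4), paste0("c", 5:12))
  a <- specific_tfs(m, des, 0.01, 0.5)
  b <- specific_tfs(m * 137.5, des, 0.01, 0.5)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-9)
  expect_equal(a$log2_fc, b$log2_fc, tolerance = 1e-9)
  expect_identical(a$pass, b$pass)
})

test_that("cutoffs are strict: a log2 fold change of exactly 1 fails", {
  # target exactly 2x background with near-zero within-group noise;
  # +/- 2^-20 perturbations keep the group means exact in binary
  eps <- 2^-20
  tvals <- c(2 + 2 * eps, 2 - 2 * eps, 2, 2)
  bvals <- c(1 + eps, 1 - eps, 1, 1)
  m <- matrix(c(tvals, bvals), 1, 8,
              dimnames = list("TF1", paste0("c", 1:8)))
  des <- group_design(paste0("c", 1:4), paste0("c", 5:8))
  call <- specific_tfs(m, des, p_cut = 0.001, lfc_cut = 1)
  expect_lt(call$p_value, 1e-6)
  expect_equal(call$log2_fc, 1, tolerance = 1e-12)
  expect_false(call$pass)  # lfc > 1 is strict
})

test_that("the exclusion filter drops listed genes only", {
  calls <- data.frame(tf = c("A", "B", "C"), p_value = 0.01,
                      log2_fc = 2, test = "welch", pass = TRUE,
                      stringsAsFactors = FALSE)
  expect_identical(filter_gene_list(calls, character()), calls)
  expect_message(kept <- filter_gene_list(calls, c("A", "C")),
                 "2 call")
  expect_equal(kept$tf, "B")
  expect_warning(expect_message(
    all_gone <- filter_gene_list(calls, c("A", "B", "C", "Zzz")),
    "3 call"), "Zzz")
  expect_equal(nrow(all_gone), 0L)
})

test_that("balanced resampling ranks planted memory drivers on top", {
  set.seed(101)
  n_tf <- 40
  cts <- c(paste0("mem", 1:3), paste0("bg", 1:20))
  planted <- paste0("TF", 1:4)
  m <- matrix(rlnorm(n_tf * 23, meanlog = 2, sdlog = 0.4), n_tf, 23,
              dimnames = list(paste0("TF", 1:n_tf), cts))
  m[planted, 1:3] <- m[planted, 1:3] * 6
  freq <- balanced_resampling(m, paste0("mem", 1:3), paste0("bg", 1:20),
                              n_reps = 100, p_cut = 0.1, seed = 5)
  expect_true(all(planted %in% freq$tf[1:8]))
  expect_true(all(freq$frequency >= 0 & freq$frequency <= 1))
  # determinism under the seed
  freq2 <- balanced_resampling(m, paste0("mem", 1:3),
                               paste0("bg", 1:20), n_reps = 100,
                               p_cut = 0.1, seed = 5)
  expect_identical(freq, freq2)
  # a TF constant across all columns can never be selected
  m["TF40", ] <- 3
  freq3 <- balanced_resampling(m, paste0("mem", 1:3),
                               paste0("bg", 1:20), n_reps = 50,
                               seed = 6)
  expect_equal(freq3$frequency[freq3$tf == "TF40"], 0)
})

test_that("Fisher overlap equals hypergeometric enumeration", {
  # identical lists of 5 in a universe of 100
  A <- paste0("T", 1:5)
  got <- fisher_overlap(A, A, 100)
  # two-sided exact p: sum of hypergeometric outcomes no more likely
  # than the observed table
  enum_p <- function(k, nA, nB, N) {
    probs <- dhyper(0:min(nA, nB), nA, N - nA, nB)
    sum(probs[probs <= dhyper(k, nA, N - nA, nB) * (1 + 1e-7)])
  }
  expect_equal(got$p_value, enum_p(5, 5, 5, 100), tolerance = 1e-10)
  expect_equal(got$n_overlap, 5L)

  # disjoint small lists in a large universe are unremarkable
  got2 <- fisher_overlap(paste0("a", 1:3), paste0("b", 1:3), 1000)
  expect_equal(got2$p_value, enum_p(0, 3, 3, 1000), tolerance = 1e-10)
  expect_gt(got2$p_value, 0.9)

  expect_error(fisher_overlap(paste0("x", 1:30), paste0("y", 1:30), 10),
               "universe smaller")
})
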