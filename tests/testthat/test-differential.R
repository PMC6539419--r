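test_that("zero imputation follows the stated rules", {
  d <- sample_design(c("s1", "s2", "s3"), rep("A", 3), 1:3)
  v <- matrix(c(0, 4, 8), 1, 3, dimnames = list("m1", d$sample_id))
  x <- abundance_matrix(v, feature_annotation("m1"), d)
  expect_equal(unname(impute_zeros(x)$values[1, ]), c(2, 4, 8))
  expect_equal(impute_zeros(x, "pseudocount", pseudocount = 1)$values[1, 1],
               1, ignore_attr = TRUE)
  # no zeros: identity
  x2 <- toy_matrix(4)
  expect_equal(impute_zeros(x2)$values, x2$values)
  # all-zero matrix is an error
  v3 <- matrix(0, 1, 3, dimnames = list("m1", d$sample_id))
  x3 <- abundance_matrix(v3, feature_annotation("m1"), d)
  expect_error(impute_zeros(x3), "all-zero")
})

test_that("fold change is the ratio of stage means, antisymmetric", {
  x <- planted_matrix(c(4, 1, 0.25))
  fc <- fold_change(x, comparison_spec("PEC", "NEC"))
  expect_equal(fc$fc, c(4, 1, 0.25))
  expect_equal(fc$log2fc, c(2, 0, -2))
  rev_fc <- fold_change(x, comparison_spec("NEC", "PEC"))
  expect_equal(fc$fc * rev_fc$fc, rep(1, 3), tolerance = 1e-12)
})

test_that("printed fold changes reproduce printed log2 values", {
  for (name in c("purine_dams", "flavonoid_dams")) {
    tab <- reference_table(name)
    dec <- attr(tab, "printed_decimals")
    recomputed <- log2(tab$fc)
    # agreement to the printed precision: within one unit in the last
    # printed decimal (the printed fold changes are themselves rounded)
    expect_true(all(abs(recomputed - tab$log2fc) <= 10^(-dec) + 1e-9),
                label = paste(name, "log2fc at printed precision"))
    expect_equal(tab$status, ifelse(tab$fc >= 2, "up", "down"))
  }
})

test_that("NIPALS PLS-DA matches the exact one-component solution", {
  set.seed(21)
  d <- toy_design(3, c("NEC", "PEC"))
  n <- 6
  v <- matrix(exp(rnorm(n * 6, 8, 0.3)), n, 6,
              dimnames = list(sprintf("m%02d", 1:n), d$sample_id))
  x <- abundance_matrix(v, feature_annotation(rownames(v)), d)
  m <- fit_plsda(x, comparison_spec("PEC", "NEC"), n_components = 1)

  # independent closed form: w proportional to X'y on the same scaling
  X <- scale(t(log2(v + 1)))
  Xc <- X[c(d$sample_id[d$stage == "PEC"], d$sample_id[d$stage == "NEC"]), ]
  y <- c(rep(1, 3), rep(0, 3)); y <- y - mean(y)
  w <- drop(crossprod(Xc, y)); w <- w / sqrt(sum(w^2))
  if (w[which(abs(w) > 1e-12)[1]] < 0) w <- -w
  expect_equal(unname(m$weights[, 1]), unname(w), tolerance = 1e-10)

  # scores separate the classes by sign for a separable toy
  sep <- planted_matrix(c(8, 6, 7), base = 50)
  ms <- fit_plsda(sep, comparison_spec("PEC", "NEC"), n_components = 1)
  grp <- ms$samples %in% sep$design$sample_id[sep$design$stage == "PEC"]
  expect_true(all(sign(ms$scores[grp, 1]) == sign(ms$scores[grp, 1][1])))
  expect_true(all(sign(ms$scores[!grp, 1]) != sign(ms$scores[grp, 1][1])))
})

test_that("deflation leaves residuals orthogonal to extracted scores", {
  for (seed in 1:5) {
    set.seed(seed)
    d <- toy_design(3, c("NEC", "PEC"))
    v <- matrix(exp(rnorm(8 * 6, 8, 0.5)), 8, 6,
                dimnames = list(sprintf("m%02d", 1:8), d$sample_id))
    x <- abundance_matrix(v, feature_annotation(rownames(v)), d)
    m <- fit_plsda(x, comparison_spec("PEC", "NEC"), n_components = 2)
    expect_lt(max(abs(crossprod(m$scores, m$residual))), 1e-8)
  }
})

test_that("VIP obeys its algebraic identity and closed-form toys", {
  # sum of squared VIP equals the feature count on random fits
  for (seed in 1:5) {
    set.seed(seed)
    d <- toy_design(3, c("NEC", "PEC"))
    p <- 5 + seed
    v <- matrix(exp(rnorm(p * 6, 8, 0.6)), p, 6,
                dimnames = list(sprintf("m%02d", 1:p), d$sample_id))
    x <- abundance_matrix(v, feature_annotation(rownames(v)), d)
    vip <- vip_scores(fit_plsda(x, comparison_spec("PEC", "NEC")))
    expect_equal(sum(vip^2), p, tolerance = 1e-6)
  }
  # two features, only one informative: VIP -> (sqrt(2), 0)
  d <- toy_design(3, c("NEC", "PEC"))
  v <- rbind(m1 = c(10, 10, 10, 80, 80, 80),
             m2 = c(30, 31, 30, 30, 31, 30))
  # make the uninformative feature exactly balanced across groups
  v["m2", ] <- c(30, 31, 32, 30, 31, 32)
  colnames(v) <- d$sample_id
  x <- abundance_matrix(v, feature_annotation(rownames(v)), d)
  vip <- vip_scores(fit_plsda(x, comparison_spec("PEC", "NEC"),
                              n_components = 1))
  expect_equal(unname(vip["m1"]), sqrt(2), tolerance = 1e-9)
  expect_equal(unname(vip["m2"]), 0, tolerance = 1e-9)
})

test_that("location test matches t-distribution oracle and conventions", {
  d <- toy_design(3, c("NEC", "PEC"))
  # identical groups: p = 1 by the degenerate convention
  v <- rbind(m1 = rep(7, 6))
  colnames(v) <- d$sample_id
  x <- abundance_matrix(v, feature_annotation("m1"), d)
  expect_equal(feature_test(x, comparison_spec("PEC", "NEC"))$p, 1)

  # large shift, tiny relative variance: p below 0.001 (t-tail oracle)
  v2 <- rbind(m1 = c(1, 2, 3, 10001, 10002, 10003))
  colnames(v2) <- d$sample_id
  x2 <- abundance_matrix(v2, feature_annotation("m1"), d)
  p2 <- feature_test(x2, comparison_spec("PEC", "NEC"))$p
  a <- log2(c(10001, 10002, 10003) + 1); b <- log2(c(1, 2, 3) + 1)
  tstat <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  df <- (var(a) / 3 + var(b) / 3)^2 /
    ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(p2, 2 * pt(abs(tstat), df, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_lt(p2, 0.001)

  # Welch equals Student when variances and group sizes match
  # (values chosen so log2(x + 1) is exactly 1..6: equal group variances)
  v3 <- rbind(m1 = 2^(1:6) - 1)
  colnames(v3) <- d$sample_id
  x3 <- abundance_matrix(v3, feature_annotation("m1"), d)
  expect_equal(feature_test(x3, comparison_spec("PEC", "NEC"), "welch")$p,
               feature_test(x3, comparison_spec("PEC", "NEC"), "student")$p,
               tolerance = 1e-12)
})

test_that("status calls honor inclusive thresholds and partition features", {
  expect_equal(call_status(2.0, vip = 1.0, use_p = FALSE), "up")
  expect_equal(call_status(3.0, vip = 0.5, use_p = FALSE), "unchanged")
  expect_equal(call_status(0.5, vip = 1.2, use_p = FALSE), "down")
  expect_equal(call_status(2.0, vip = 1.0, p = 0.04), "up")
  expect_equal(call_status(2.0, vip = 1.0, p = 0.05), "unchanged")

  set.seed(3)
  fc <- exp(rnorm(50)); vip <- abs(rnorm(50, 1, 0.5)); p <- runif(50)
  st <- call_status(fc, vip, p)
  expect_equal(sum(st == "up") + sum(st == "down") +
                 sum(st == "unchanged"), 50)
  expect_true(all(st[fc >= 2 & vip >= 1 & p < 0.05] == "up"))
})

test_that("DEG calls use |log2FC| >= 1 with FDR and pass through tables", {
  pre <- data.frame(feature_id = c("g1", "g2"), log2fc = c(3.61, 0.2),
                    status = c("up", "unchanged"), stringsAsFactors = FALSE)
  out <- deg_analysis(precomputed = pre)
  expect_equal(out$status, c("up", "unchanged"))
  expect_equal(out$log2fc, c(3.61, 0.2))

  x <- planted_matrix(c(12, 1.1, 0.05), base = 200)
  deg <- deg_analysis(x, comparison_spec("PEC", "NEC"))
  expect_equal(deg$status, c("up", "unchanged", "down"))
})

test_that("Venn partition yields seven disjoint regions covering the union", {
  p <- venn_partition(list(A = c("a", "b"), B = c("b", "c"),
                           C = c("b", "d")))
  expect_equal(p[["A&B&C"]], "b")
  expect_equal(p[["A_only"]], "a")
  all_members <- unlist(p)
  expect_equal(sort(unname(all_members)), sort(c("a", "b", "c", "d")))
  expect_equal(anyDuplicated(all_members), 0)

  q <- venn_partition(list(A = "x", B = "y", C = "z"))
  expect_equal(lengths(q)[c("A_only", "B_only", "C_only")],
               c(A_only = 1L, B_only = 1L, C_only = 1L))
  expect_equal(sum(lengths(q)), 3)

  set.seed(5)
  sets <- lapply(1:3, function(i) sample(letters, 12))
  names(sets) <- c("A", "B", "C")
  r <- venn_partition(sets)
  expect_equal(sum(lengths(r)), length(unique(unlist(sets))))
})

test_that("class composition counts, fractions and ordering", {
  ann <- feature_annotation(sprintf("m%d", 1:10),
                            feature_class = c(rep("Flavone", 4),
                                              rep("Lipid", 3),
                                              rep("Amino acid", 3)))
  comp <- class_composition(sprintf("m%d", 1:10), ann)
  expect_equal(comp$feature_class[1], "Flavone")
  expect_equal(comp$fraction[1], 0.4)
  expect_equal(sum(comp$fraction), 1)
  expect_equal(nrow(class_composition(character(), ann)), 0)
  # unannotated features fall back to "other"
  comp2 <- class_composition(c("m1", "zz"), ann)
  expect_true("other" %in% comp2$feature_class)
})

test_that("hierarchical clustering uses 1-r distance with average linkage", {
  d <- toy_design(2, c("A", "B"))
  v <- rbind(m1 = c(1, 2, 3, 4), m2 = c(2, 4, 6, 8),
             m3 = c(4, 3, 2, 1), m4 = c(5, 5, 5, 5))
  colnames(v) <- d$sample_id
  x <- abundance_matrix(v, feature_annotation(rownames(v)), d)
  hc <- hca_order(x, transform = "none", cluster_samples = FALSE)
  tree <- hc$feature_tree
  # identical profiles merge first at height 0
  first <- sort(rownames(v)[-tree$merge[1, ]])
  expect_equal(first, c("m1", "m2"))
  expect_equal(tree$height[1], 0, tolerance = 1e-12)
  # exhaustive oracle: distances are 1 - pearson, constant row at 2
  dm <- as.matrix(stats::cophenetic(tree))
  expect_equal(dm["m1", "m2"], 0, tolerance = 1e-12)
  expect_equal(dm["m4", "m1"], 2, tolerance = 1e-12)
  # anti-correlated profile sits at distance 2 from m1/m2
  expect_equal(1 - cor(v["m1", ], v["m3", ]), 2, tolerance = 1e-12)
  expect_error(hca_order(x, features = c("m1", "zz")), "unknown")
})
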