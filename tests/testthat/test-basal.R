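make_decomposition <- function(n_genes = 30, n_im = 4, n_samples = 40,
                               seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(n_genes * n_im), n_genes, n_im,
              dimnames = list(sprintf("g%02d", 1:n_genes),
                              sprintf("iM%02d", 1:n_im)))
  A <- matrix(rnorm(n_im * n_samples, sd = 3), n_im, n_samples,
              dimnames = list(colnames(M), sprintf("s%02d", 1:n_samples)))
  list(M = M, A = A)
}

test_that("member genes come from the absolute-weight threshold rule", {
  M <- matrix(0, 50, 2, dimnames = list(sprintf("g%02d", 1:50),
                                        c("k1", "k2")))
  expect_warning(mg <- member_genes(M, "k1"), "all-zero")
  expect_length(mg, 0)

  set.seed(4)
  M[, 2] <- rnorm(50, sd = 0.02)
  M["g03", 2] <- 5
  expect_equal(member_genes(M, "k2"), "g03")

  M[, 1] <- rnorm(50)
  w <- abs(M[, 1])
  expect_equal(member_genes(M, "k1"),
               rownames(M)[w > mean(w) + 2 * sd(w)])
})

test_that("explained variance matches the centered rank-one residual", {
  d <- make_decomposition(n_im = 1)
  X <- d$M %*% d$A
  expect_equal(explained_variance(X, d$M, d$A, "iM01", rownames(X)), 1)

  d2 <- make_decomposition(n_im = 2, seed = 2)
  d2$A["iM02", ] <- 0
  X2 <- d2$M %*% d2$A + matrix(rnorm(length(d2$M[, 1]) * ncol(d2$A)),
                               nrow(d2$M))
  expect_equal(explained_variance(X2, d2$M, d2$A, "iM02", rownames(X2)), 0)

  # independent loop-based recomputation on a small gene set
  genes <- rownames(X2)[1:7]
  r2 <- explained_variance(X2, d2$M, d2$A, "iM01", genes)
  num <- 0; den <- 0
  for (g in genes) {
    x <- X2[g, ] - mean(X2[g, ])
    r <- d2$M[g, "iM01"] * d2$A["iM01", ]
    r <- r - mean(r)
    num <- num + sum((x - r)^2)
    den <- den + sum(x^2)
  }
  expect_equal(r2, 1 - num / den, tolerance = 1e-12)

  expect_error(explained_variance(X2, d2$M, d2$A, "iM01", character()),
               "empty")
})

test_that("direction assignment anchors on KO samples with tie fallback", {
  a <- setNames(c(1:10, 20, 0), c(paste0("r", 1:10), "ko_hi", "ko_lo"))
  refs <- paste0("r", 1:10)
  expect_equal(assign_direction(a, refs, "ko_hi"), 1)
  expect_equal(assign_direction(a, refs, "ko_lo"), -1)

  a["tie"] <- median(a[refs])
  expect_warning(d <- assign_direction(a, refs, "tie"), "median")
  expect_equal(d, -1)

  expect_equal(assign_direction(a, refs, annotated_direction = 1), 1)
  expect_error(assign_direction(a, refs), "annotated")
  expect_error(assign_direction(a, character(), "ko_hi"), "non-empty")
})

test_that("basal transform shifts by reference quantiles and flips positives", {
  refs <- sprintf("s%03d", 1:101)
  A <- matrix(0:100, 1, 101, dimnames = list("iM01", refs))
  M <- matrix(1, 3, 1, dimnames = list(paste0("g", 1:3), "iM01"))

  up <- basal_transform(M, A, c(iM01 = 1), refs)
  expect_equal(unname(up$offsets), 95)
  expect_equal(unname(up$A["iM01", c("s101", "s001")]), c(-5, 95))
  expect_equal(up$M[, 1], -M[, 1])

  const <- basal_transform(M, A * 0 + 7, c(iM01 = -1), refs)
  expect_true(all(const$A == 0))
  expect_equal(const$M, M)

  expect_error(basal_transform(M, A, c(other = 1), refs), "cover")
  expect_warning(basal_transform(M, A[, 1:10, drop = FALSE], c(iM01 = -1),
                                 refs[1:10]), "fewer than 20")
})

test_that("basal transform is invertible and algebraically sign-consistent", {
  d <- make_decomposition(seed = 3)
  refs <- colnames(d$A)[1:30]
  dirs <- setNames(c(1, -1, 1, -1), rownames(d$A))
  b <- basal_transform(d$M, d$A, dirs, refs)

  inv <- basal_invert(b)
  expect_equal(inv$A, d$A, tolerance = 1e-12)
  expect_equal(inv$M, d$M, tolerance = 1e-12)

  # reconstruction from transformed matrices equals M (A - offset) for
  # both directions: the +1 case flips the sign of M and A together
  for (k in rownames(d$A)) {
    lhs <- b$M[, k] %o% b$A[k, ]
    rhs <- d$M[, k] %o% (d$A[k, ] - b$offsets[[k]])
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }

  # at most 5% of reference samples (plus one) fall below zero
  neg <- rowMeans(b$A[, refs] < 0)
  expect_true(all(neg <= 0.05 + 1 / length(refs)))
})

test_that("re-running the transform on transformed data only re-shifts", {
  d <- make_decomposition(seed = 8)
  refs <- colnames(d$A)
  dirs <- setNames(c(-1, 1, -1, 1), rownames(d$A))
  b1 <- basal_transform(d$M, d$A, dirs, refs)
  # on the basal scale activity rises with value, so directions recompute
  # to -1 everywhere and a second pass only subtracts small 5% offsets
  dirs2 <- setNames(rep(-1, 4), rownames(d$A))
  b2 <- basal_transform(b1$M, b1$A, dirs2, refs)
  expect_equal(b2$M, b1$M)
  for (k in rownames(d$A))
    expect_equal(b2$A[k, ], b1$A[k, ] - b2$offsets[[k]], tolerance = 1e-12)
})

test_that("imodulon matching recovers permutations and sign flips", {
  d <- make_decomposition(n_genes = 60, n_im = 6, seed = 5)
  perm <- c(3, 1, 6, 2, 5, 4)
  M2 <- d$M[, perm]
  colnames(M2) <- sprintf("new%02d", 1:6)
  flip <- c(1, -1, 1, -1, -1, 1)
  M2 <- sweep(M2, 2, flip, "*")
  res <- match_imodulons(d$M, M2)
  expect_true(all(res$matched))
  expect_equal(attr(res, "matched_fraction"), 1)
  expect_equal(abs(res$r), rep(1, 6), tolerance = 1e-12)
  m <- match(res$k2, colnames(M2))
  expect_equal(colnames(d$M)[perm][m], res$k1)

  expect_error(match_imodulons(d$M[1:5, ], M2[1:5, ]), "shared genes")
})

test_that("differential activity flags only real shifts", {
  d <- make_decomposition(n_im = 5, n_samples = 32, seed = 6)
  refs <- colnames(d$A)[1:20]
  dirs <- setNames(rep(-1, 5), rownames(d$A))
  b <- basal_transform(d$M, d$A, dirs, refs)
  g1 <- colnames(d$A)[21:26]
  g2 <- colnames(d$A)[27:32]

  expect_error(differential_activity(b, g1, c(g2, g1[1])), "overlap")

  null_res <- differential_activity(b, g1, g2, n_permutations = 499,
                                    seed = 1)
  b2 <- b
  b2$A[2, g1] <- b2$A[2, g1] + 25
  shifted <- differential_activity(b2, g1, g2, n_permutations = 499,
                                   seed = 1)
  expect_true(shifted$flagged[2])
  expect_false(any(null_res$flagged))
})

test_that("identical groups are never flagged", {
  d <- make_decomposition(n_im = 3, n_samples = 12, seed = 7)
  refs <- colnames(d$A)
  b <- suppressWarnings(   # few reference samples by design here
    basal_transform(d$M, d$A, setNames(rep(-1, 3), rownames(d$A)), refs))
  res <- differential_activity(b, colnames(d$A)[1:6], colnames(d$A)[7:12],
                               n_permutations = 199, seed = 2)
  # exchangeable halves of one sample: no flag expected
  expect_false(any(res$flagged))
})

test_that("operon-level differential expression aggregates gene fold changes", {
  set.seed(12)
  genes <- sprintf("g%02d", 1:9)
  X <- matrix(rnorm(9 * 6, mean = 5, sd = 0.1), 9, 6,
              dimnames = list(genes, c(paste0("a", 1:3), paste0("b", 1:3))))
  omap <- data.frame(gene = genes,
                     operon = rep(c("op1", "op2", "op3"), each = 3))
  a <- paste0("a", 1:3); b <- paste0("b", 1:3)

  same <- diff_expressed_operons(X, omap, a, a[c(2, 3, 1)])
  expect_false(any(same$de))

  X2 <- X
  X2[omap$gene[omap$operon == "op2"], a] <-
    X2[omap$gene[omap$operon == "op2"], a] + 4
  res <- diff_expressed_operons(X2, omap, a, b)
  expect_true(res$de[res$operon == "op2"])
  expect_false(any(res$de[res$operon != "op2"]))

  # operon fold change is the mean of member-gene fold changes
  lfc_by_gene <- rowMeans(X2[1:3, a]) - rowMeans(X2[1:3, b])
  expect_equal(res$log2fc[res$operon == "op1"], mean(lfc_by_gene),
               tolerance = 1e-12)

  omap_extra <- rbind(omap, data.frame(gene = "missing", operon = "op4"))
  expect_warning(diff_expressed_operons(X2, omap_extra, a, b), "skipped")
  expect_error(diff_expressed_operons(X2, omap, a[1], b), "replicates")
  expect_error(
    diff_expressed_operons(X2, rbind(omap, omap[1, ]), a, b), "more than one")
})
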