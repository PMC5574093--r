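test_that("probe filtering keeps the closed 300-20000 window", {
  v <- c(250, 299, 300, 5000, 20000, 20001, 25000)
  expect_equal(filter_probes(v),
               c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("probe collapse takes per-gene medians", {
  vals <- c(350, 400, 1000, 700, 400, 600)
  genes <- c("a", "a", "a", "b", "c", "c")
  m <- collapse_probes(vals, genes)
  expect_equal(unname(m["a"]), 400)
  expect_equal(unname(m["b"]), 700)     # single probe -> itself
  expect_equal(unname(m["c"]), 500)     # even count -> midpoint
})

test_that("z-scores standardize with population SD and affine invariance", {
  v <- c(1, 2, 3)
  z <- zscore(v)
  expect_equal(z[2], 0)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  expect_equal(zscore(10 * v + 3), z)
  expect_error(zscore(c(5, 5, 5)), "zero variance")
})

test_that("KS running enrichment reproduces the hand-computed example", {
  # N = 4 genes, bound at ranks 1 and 2:
  # D = (0.25, 0.5, 0.25, 0) -> d = 0.5 at rank 2
  ks <- ks_running_enrichment(c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(ks$curve, c(0.25, 0.5, 0.25, 0))
  expect_equal(ks$d, 0.5)
  expect_equal(ks$rank_at_max, 2L)
  expect_false(ks$degenerate)

  # all genes bound: degenerate, flat curve
  ks0 <- ks_running_enrichment(rep(TRUE, 6))
  expect_true(ks0$degenerate)
  expect_equal(ks0$p_value, 1)
  expect_true(ks_running_enrichment(rep(FALSE, 6))$degenerate)
})

test_that("the running score telescopes to zero and d is rank-invariant", {
  set.seed(12)
  for (i in 1:20) {
    N <- sample(20:400, 1)
    B <- sample(seq_len(N - 1), 1)
    fl <- rep(FALSE, N)
    fl[sample(N, B)] <- TRUE
    ks <- ks_running_enrichment(fl)
    expect_equal(ks$curve[N], 0, tolerance = 1e-12)
    expect_lte(abs(ks$d), 1)
  }
  # d depends only on the ranking, not the fold-change magnitudes
  fc1 <- c(g1 = 0.2, g2 = 0.5, g3 = 1.1, g4 = 3)
  fc2 <- c(g1 = 0.01, g2 = 0.9, g3 = 1.5, g4 = 100)
  expect_identical(rank_genes(fc1, "signed"), rank_genes(fc2, "signed"))
})

test_that("ranking modes sort as documented with deterministic ties", {
  fc <- c(gB = 0.5, gA = 0.5, gC = 2, gD = 1.01)
  expect_equal(rank_genes(fc, "signed"), c("gA", "gB", "gD", "gC"))
  expect_equal(rank_genes(fc, "absolute"), c("gA", "gB", "gC", "gD"))
})

test_that("permutation p agrees with the asymptotic p at moderate n", {
  set.seed(9)
  fl <- rep(FALSE, 300)
  fl[sample(300, 40)] <- TRUE
  ks <- ks_running_enrichment(fl, n_perm = 400, seed = 4)
  expect_gt(ks$p_perm, 0.05)
  agree <- abs(ks$p_perm - ks$p_value)
  expect_lt(agree, 0.35)
})

test_that("Welch statistics match stats::t.test gene by gene", {
  set.seed(2)
  expr <- data.frame(gene_id = sprintf("g%02d", 1:8),
                     matrix(2^(rnorm(8 * 7, 10, 1)), nrow = 8))
  names(expr)[2:8] <- c(sprintf("wt_%d", 1:4), sprintf("mut_%d", 1:3))
  de <- differential_expression(expr)
  for (i in c(1, 5, 8)) {
    ref <- stats::t.test(as.numeric(expr[i, 6:8]),
                         as.numeric(expr[i, 2:5]))
    expect_equal(de$p_value[i], ref$p.value, tolerance = 1e-10)
  }
  expect_equal(de$fold_change,
               rowMeans(expr[, 6:8]) / rowMeans(expr[, 2:5]),
               tolerance = 1e-12)
})

test_that("bound flags honor strand-aware windows per region class", {
  genes <- rbind(mk_gene("gp", "chr1", "+", 50000, 60000),
                 mk_gene("gm", "chr1", "-", 100000, 110000))
  # peak 1 kb upstream of the + TSS -> promoter only
  pk_prom <- genomic_intervals("chr1", 48900, 49100)
  fl <- assign_bound_flags(genes, pk_prom)
  expect_true(fl$promoter[1])
  expect_false(fl$gene_body[1])
  expect_false(fl$downstream[1])
  expect_true(fl$gene_region[1])
  expect_false(any(unlist(fl[2, ])))

  # peak wholly inside the gene body, past the promoter's downstream reach
  pk_body <- genomic_intervals("chr1", 55000, 55200)
  fl2 <- assign_bound_flags(genes, pk_body)
  expect_true(fl2$gene_body[1])
  expect_false(fl2$promoter[1])

  # minus-strand gene: upstream = larger coordinates
  pk_m <- genomic_intervals("chr1", 111000, 111200)
  fl3 <- assign_bound_flags(genes, pk_m)
  expect_true(fl3$promoter[2])
  expect_false(fl3$downstream[2])

  # no peaks: everything FALSE
  fl4 <- assign_bound_flags(genes, pk_prom[0, ])
  expect_false(any(unlist(fl4)))
})

test_that("target table accounting satisfies its arithmetic identities", {
  set.seed(21)
  n <- 60
  de <- data.frame(gene_id = sprintf("g%02d", 1:n),
                   fold_change = exp(rnorm(n, 0, 0.5)),
                   p_value = runif(n))
  flags <- data.frame(promoter = runif(n) < 0.3,
                      gene_body = runif(n) < 0.4,
                      downstream = runif(n) < 0.1)
  flags$gene_region <- flags$promoter | flags$gene_body | flags$downstream
  tt <- build_target_table(de, flags)
  tab <- tt$table
  expect_equal(tab["upregulated", "total"] + tab["downregulated", "total"],
               tab["total", "total"])
  expect_equal(tab["total", "gene_region"] + tab["total", "none"],
               tab["total", "total"])

  # no gene passes: all zeros
  de0 <- de
  de0$p_value <- 1
  expect_true(all(build_target_table(de0, flags)$table == 0))

  # promoter-only binding: none column empty, promoter equals gene region
  flags1 <- data.frame(promoter = rep(TRUE, n), gene_body = FALSE,
                       downstream = FALSE, gene_region = TRUE)
  tt1 <- build_target_table(de, flags1)
  expect_equal(unname(tt1$table["total", "none"]), 0)
  expect_equal(tt1$table["total", "promoter"],
               tt1$table["total", "gene_region"])
})

test_that("published marginal counts are reproduced exactly by expansion", {
  counts <- read_table(system.file("extdata", "nipbl_mef_target_counts.tsv",
                                   package = "cohesinscape"),
                       required = c("direction", "total", "gene_region",
                                    "promoter", "gene_body", "downstream",
                                    "none"))
  fx <- expand_target_counts(counts)
  tt <- build_target_table(fx$de, fx$flags, fold_threshold = 1.2,
                           p_threshold = 0.05)
  expect_equal(unname(tt$table["upregulated", ]),
               c(62, 30, 14, 22, 6, 32))
  expect_equal(unname(tt$table["downregulated", ]),
               c(156, 85, 47, 61, 14, 71))
  expect_equal(tt$n_significant, 218)
  expect_equal(tt$n_bound, 115)
})
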