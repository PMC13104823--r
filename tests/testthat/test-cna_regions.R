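test_that("per-gene CNA summaries bin at the strict -0.4/+0.4 thresholds", {
  v <- rbind(loss = c(-1, -1, 0, 0),
             edge = c(-1, -1, -1, 0, 0) [1:4] * 0,   # placeholder, replaced below
             gain = c(1, 1, 1, 0))
  v["edge", ] <- c(-2, 0, 0, 0.4)                    # mean exactly -0.4
  colnames(v) <- paste0("T", 1:4)
  s <- gene_cna_summary(v)
  expect_equal(s$mean_cna[s$gene_id == "loss"], -0.5)
  expect_identical(s$bin[s$gene_id == "loss"], "loss")
  expect_identical(s$bin[s$gene_id == "edge"], "nc")  # strict inequality
  expect_identical(s$bin[s$gene_id == "gain"], "gain")

  vna <- matrix(NA_real_, 1, 4, dimnames = list("gone", paste0("T", 1:4)))
  s2 <- gene_cna_summary(rbind(v, vna))
  expect_true(s2$excluded[s2$gene_id == "gone"])

  set.seed(4)
  r <- matrix(sample(seq(-2, 2, 0.5), 200, TRUE), 50, 4,
              dimnames = list(sprintf("g%02d", 1:50), paste0("T", 1:4)))
  s3 <- gene_cna_summary(r)
  mu <- rowMeans(r)
  oracle <- ifelse(mu < -0.4, "loss", ifelse(mu > 0.4, "gain", "nc"))
  expect_identical(s3$bin, unname(oracle))
})

test_that("uniform and tolerance-rule regions are called as specified", {
  # 120 genes all at -0.5: one region covering everything
  W <- call_windows(rep(-0.5, 120), min_genes = 100)
  expect_equal(unname(W), matrix(c(1L, 120L), 1))

  # 5 interspersed genes at -0.37 are tolerated while the run mean stays <= -0.4
  x <- rep(-0.5, 125)
  x[c(20, 45, 70, 95, 120)] <- -0.37
  W2 <- call_windows(x, min_genes = 100)
  expect_equal(unname(W2), matrix(c(1L, 125L), 1))
  expect_lte(mean(x), -0.4)

  # a gene at the tolerance bound (-0.35) can never be inside a region
  x3 <- c(rep(-0.5, 60), -0.35, rep(-0.5, 60))
  W3 <- call_windows(x3, min_genes = 50)
  expect_equal(unname(W3), rbind(c(1L, 60L), c(62L, 121L)))
})

test_that("the caller matches the exhaustive window-enumeration oracle", {
  # hand-sized 12-gene chromosome, min_genes = 3
  x <- c(-0.5, -0.5, -0.38, -0.6, -0.2, -0.5, -0.45, -0.37, -0.5, -0.1,
         -0.55, -0.5)
  expect_equal(call_windows(x, 3), enum_loss_windows(x, 3))

  set.seed(42)
  for (rep in 1:200) {
    n <- sample(5:60, 1)
    xs <- round(runif(n, -0.8, 0.2), 2)
    mg <- sample(1:5, 1)
    expect_equal(call_windows(xs, mg), enum_loss_windows(xs, mg),
                 info = sprintf("instance %d (n=%d, min_genes=%d)", rep, n, mg))
  }
})

test_that("every returned region satisfies its defining predicates", {
  set.seed(15)
  n_checked <- 0
  for (rep in 1:30) {
    n <- sample(120:300, 1)
    x <- round(runif(n, -0.7, -0.2), 2)
    n_ann <- length(x)
    ann <- data.frame(gene_id = sprintf("g%03d", 1:n_ann), chromosome = "chr1",
                      start = (1:n_ann) * 1000L, end = (1:n_ann) * 1000L + 500L)
    summ <- data.frame(gene_id = ann$gene_id, mean_cna = x, n_obs = 5L,
                       bin = "x", excluded = FALSE)
    res <- call_loss_regions(summ, ann, "T", min_genes = 20)
    if (nrow(res$primary)) for (k in seq_len(nrow(res$primary))) {
      n_checked <- n_checked + 1
      idx <- match(unlist(res$primary$genes[k]), ann$gene_id)
      expect_true(all(diff(idx) == 1))                   # contiguous
      expect_gte(length(idx), 20)
      expect_lte(mean(x[idx]), -0.4 + 1e-9)
      expect_true(all(x[idx] < -0.35))
    }
  }
  expect_gt(n_checked, 0)
})

test_that("region calling is invariant to chromosome processing order", {
  set.seed(6)
  x1 <- round(runif(80, -0.7, 0), 2)
  x2 <- round(runif(80, -0.7, 0), 2)
  mk <- function(chroms, xs) {
    n <- length(xs)
    ann <- data.frame(gene_id = sprintf("%s_g%02d", chroms, 1:n),
                      chromosome = chroms, start = (1:n) * 1000L,
                      end = (1:n) * 1000L + 500L)
    summ <- data.frame(gene_id = ann$gene_id, mean_cna = xs, n_obs = 5L,
                       bin = "x", excluded = FALSE)
    list(ann = ann, summ = summ)
  }
  a <- mk(rep("chr1", 80), x1); b <- mk(rep("chr2", 80), x2)
  joint <- call_loss_regions(rbind(a$summ, b$summ), rbind(a$ann, b$ann),
                             "T", min_genes = 10)
  joint_rev <- call_loss_regions(rbind(b$summ, a$summ), rbind(b$ann, a$ann),
                                 "T", min_genes = 10)
  key <- function(r) sort(sprintf("%s:%d-%d", r$chromosome, r$start, r$end))
  expect_identical(key(joint$primary), key(joint_rev$primary))
  # row order of the inputs is irrelevant: positions drive the ordering
  perm <- sample(nrow(a$summ))
  shuffled <- call_loss_regions(a$summ[perm, ], a$ann, "T", min_genes = 10)
  straight <- call_loss_regions(a$summ, a$ann, "T", min_genes = 10)
  expect_identical(key(shuffled$primary), key(straight$primary))
})

test_that("overlap rescue requires full containment in another cancer", {
  primary <- data.frame(cancer_code = "LUSC", chromosome = "chr21",
                        start = 1000L, end = 120000L, n_genes = 114L,
                        mean_cna = -0.5, rule = "primary",
                        stringsAsFactors = FALSE)
  primary$genes <- list(sprintf("g%03d", 1:114))
  cand <- data.frame(
    cancer_code = c("STAD", "STAD", "STAD", "LUSC"),
    chromosome = c("chr21", "chr21", "chr5", "chr21"),
    start = c(2000L, 60000L, 2000L, 2000L),
    end = c(80000L, 180000L, 80000L, 80000L),
    n_genes = c(67L, 50L, 40L, 67L),
    mean_cna = c(-0.45, -0.45, -0.45, -0.45),
    rule = "candidate", stringsAsFactors = FALSE)
  cand$genes <- list(sprintf("g%03d", 2:68), sprintf("g%03d", 60:109),
                     sprintf("h%03d", 1:40), sprintf("g%03d", 2:68))
  out <- rescue_overlapping_regions(cand, primary)
  # contained run from another cancer: rescued; partial overlap: not;
  # different chromosome: not; same cancer as the primary: not
  expect_equal(nrow(out), 1L)
  expect_identical(out$cancer_code, "STAD")
  expect_equal(out$start, 2000L)
  expect_identical(out$rule, "overlap_rescued")
  expect_match(out$rescued_by, "^LUSC:chr21")
})

test_that("region overlap reports interval intersection and shared genes", {
  a <- data.frame(chromosome = "chr1", start = 101L, end = 500L)
  a$genes <- list(c("g1", "g2", "g3"))
  expect_equal(region_overlap(a, a)$containment_fraction, 1.0)
  expect_identical(region_overlap(a, a)$shared_genes, c("g1", "g2", "g3"))

  b <- data.frame(chromosome = "chr1", start = 601L, end = 700L)
  b$genes <- list(c("g9"))
  ov <- region_overlap(a, b)
  expect_equal(ov$shared_bp, 0L)
  expect_equal(ov$containment_fraction, 0)
  expect_identical(ov$shared_genes, character())

  inner <- data.frame(chromosome = "chr1", start = 201L, end = 300L)
  inner$genes <- list(c("g2"))
  ov2 <- region_overlap(a, inner)
  expect_equal(ov2$shared_bp, 100L)
  expect_equal(ov2$containment_fraction, 1.0)

  c2 <- data.frame(chromosome = "chr2", start = 101L, end = 500L)
  c2$genes <- list(c("g1"))
  expect_equal(region_overlap(a, c2)$shared_bp, 0L)
})
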