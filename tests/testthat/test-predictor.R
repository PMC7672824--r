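coords <- function(n, dim = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * dim), n, dim)
  rownames(m) <- sprintf("N%03d", seq_len(n))
  m
}

test_that("fixed KNN matches a full-sort oracle with id tie-breaking", {
  set.seed(51)
  for (rep in 1:100) {
    n <- sample(3:30, 1)
    train <- coords(n, seed = sample.int(1e6, 1))
    q <- rnorm(ncol(train))
    k <- sample(n, 1)
    nb <- nearest_neighbors_fixed(q, train, k)
    expect_equal(nb$protein_id, oracle_knn(q, train, k))
    expect_false(is.unsorted(nb$distance))
  }
  train <- rbind(a = c(0, 1), b = c(1, 0), c = c(1, 0))
  nb <- nearest_neighbors_fixed(c(0, 0), train, 2)
  expect_equal(nb$protein_id, c("a", "b"))  # tie at distance 1 -> id order
  expect_error(nearest_neighbors_fixed(c(0, 0), train, 4), "exceeds")
})

test_that("the dynamic threshold is a quartile of training NN distances", {
  # equidistant grid: every NN distance is 1, any quartile is 1
  train <- cbind(seq(0, 5), 0)
  rownames(train) <- letters[1:6]
  for (q in c("Q1", "Q2", "Q3")) {
    expect_equal(dynamic_distance_threshold(train, q), 1)
  }
  # NN-distance multiset {1,2,3,4} -> Q2 = 2.5 by linear interpolation
  pts <- c(0, 1, 10, 12, 30, 33, 60, 64)
  train <- cbind(pts, 0)
  rownames(train) <- letters[1:8]
  expect_equal(dynamic_distance_threshold(train, "Q2"), 2.5)
  expect_equal(dynamic_distance_threshold(train, "Q1"),
               unname(quantile(c(1, 1, 2, 2, 3, 3, 4, 4), 0.25)))
  expect_error(dynamic_distance_threshold(train[1, , drop = FALSE]), "2")
})

test_that("dynamic selection is a strict-inequality filter", {
  set.seed(53)
  for (rep in 1:100) {
    train <- coords(sample(3:25, 1), seed = sample.int(1e6, 1))
    q <- rnorm(ncol(train))
    thr <- runif(1, 0.1, 3)
    nb <- nearest_neighbors_dynamic(q, train, thr)
    expect_equal(nb$protein_id, oracle_dynamic(q, train, thr))
    expect_true(all(nb$distance < thr))
  }
  train <- coords(5)
  exact <- sqrt(sum((train[1, ] - train[2, ])^2))
  nb <- nearest_neighbors_dynamic(train[2, ], train[-2, , drop = FALSE], exact)
  expect_false("N001" %in% nb$protein_id)  # boundary point excluded
  empty <- nearest_neighbors_dynamic(rnorm(3) + 100, train, 0.1)
  expect_equal(nrow(empty), 0)
})

test_that("hybrid falls back to fixed-k exactly when dynamic is empty", {
  set.seed(57)
  train <- coords(10)
  close_q <- train[1, ] + 1e-4
  far_q <- train[1, ] + 100
  thr <- dynamic_distance_threshold(train, "Q3")
  expect_equal(hybrid_neighbors(close_q, train, 3, thr),
               nearest_neighbors_dynamic(close_q, train, thr))
  expect_equal(hybrid_neighbors(far_q, train, 3, thr),
               nearest_neighbors_fixed(far_q, train, 3))
})

test_that("voting weights follow the three closed forms with an epsilon clamp", {
  expect_equal(voting_weight(c(0.5, 7), "equal"), c(1, 1))
  expect_equal(voting_weight(2, "inverse"), 0.5)
  expect_equal(voting_weight(4, "sqrt_inverse"), 0.5)
  expect_equal(voting_weight(0, "inverse"), 1e9)  # clamped, finite
  expect_true(is.finite(voting_weight(0, "sqrt_inverse")))
  expect_error(voting_weight(-1, "equal"), ">= 0")
})

test_that("FunFam overlap is Jaccard with empty/zero-overlap exclusion", {
  expect_equal(funoverlap_weight(c("F1", "F2"), c("F1", "F2")), 1)
  expect_equal(funoverlap_weight(c("F1", "F2"), c("F2", "F3")), 1 / 3)
  expect_equal(funoverlap_weight(c("F1", "F2"), c("F2", "F3"),
                                 method = "query_fraction"), 1 / 2)
  expect_equal(funoverlap_weight(c("F1"), c("F2")), 0)   # disjoint -> exclude
  expect_equal(funoverlap_weight(character(), c("F1")), 0)
  expect_equal(funoverlap_weight(c("F1"), character()), 0)
})

test_that("FunFam tables are E-value filtered at read time", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# header", "p1\tF1\t1e-9", "p1\tF2\t1e-3", "p2\tF3\t1e-6"),
             path)
  ff <- read_funfams(path)
  expect_equal(ff$p1, "F1")
  expect_equal(ff$p2, "F3")
})

test_that("vote equals a nested-loop oracle and errors on missing records", {
  dag <- fig9_dag()
  ann <- close_annotations(dag, list(
    n1 = c("GO:0000004"), n2 = c("GO:0000004", "GO:0000006"),
    n3 = c("GO:0000005")
  ))
  nb <- data.frame(protein_id = c("n1", "n2", "n3"),
                   weight = c(1.5, 0.8, 1.2))
  s <- vote(nb, ann)
  expect_equal(s, oracle_vote(nb, ann)[names(s)])
  expect_equal(unname(s["GO:0000004"]), 2.3)
  expect_error(vote(data.frame(protein_id = "zz", weight = 1), ann), "zz")

  set.seed(61)
  for (rep in 1:30) {
    dag <- random_dag(sample(8:30, 1))
    terms <- setdiff(dag$terms$id, dag$roots)
    ann <- lapply(1:6, function(i) sample(terms, sample(1:4, 1)))
    names(ann) <- sprintf("n%d", 1:6)
    ann <- close_annotations(dag, ann)
    nb <- data.frame(protein_id = sample(names(ann), 4),
                     weight = runif(4, 0.1, 3))
    s <- vote(nb, ann)
    o <- oracle_vote(nb, ann)
    expect_equal(s[sort(names(s))], o[sort(names(o))], tolerance = 1e-12)
  }
})

test_that("propagation reproduces the worked parent weights and the oracle", {
  dag <- fig9_dag()
  child_scores <- c("GO:0000004" = 2.3, "GO:0000005" = 1.2)
  s_sum <- propagate_scores(child_scores, dag, "sum")
  s_max <- propagate_scores(child_scores, dag, "max")
  expect_equal(unname(s_sum["GO:0000002"]), 3.5)
  expect_equal(unname(s_max["GO:0000002"]), 2.3)
  expect_false("GO:0000001" %in% names(s_sum))  # roots accumulate nothing

  # flat DAG: all scored terms are leaves directly under the root
  flat <- go_dag(go_id(1:4),
                 parents = list(character(), "GO:0000001", "GO:0000001",
                                "GO:0000001"))
  s <- c("GO:0000002" = 1, "GO:0000003" = 2, "GO:0000004" = 0.5)
  expect_equal(propagate_scores(s, flat, "sum")[names(s)], s)

  expect_error(propagate_scores(c("GO:0099999" = 1), dag), "not in DAG")

  set.seed(63)
  for (mode in c("sum", "max")) {
    for (rep in 1:25) {
      dag <- random_dag(sample(8:40, 1))
      terms <- setdiff(dag$terms$id, dag$roots)
      sc <- stats::setNames(runif(min(5, length(terms)), 0.1, 3),
                            sample(terms, min(5, length(terms))))
      got <- propagate_scores(sc, dag, mode)
      want <- oracle_propagate(sc, dag, mode)
      expect_equal(got[sort(names(got))], want[sort(names(want))],
                   tolerance = 1e-9)
    }
  }
})

test_that("unique-descendant Sum counts each descendant once in diamonds", {
  # diamond: GO:4 under both GO:2 and GO:3, which sit under root GO:1
  dag <- go_dag(go_id(1:5),
                parents = list(character(), "GO:0000001", "GO:0000001",
                               c("GO:0000002", "GO:0000003"), "GO:0000002"))
  sc <- c("GO:0000004" = 1, "GO:0000005" = 2)
  # path-counting: GO:2 gets GO:4 once and GO:5 once
  per_path <- propagate_scores(sc, dag, "sum")
  expect_equal(unname(per_path["GO:0000002"]), 3)
  per_desc <- propagate_scores(sc, dag, "sum", unique_descendants = TRUE)
  expect_equal(per_desc, per_path[names(per_desc)])  # tree-like here

  # true diamond: GO:4 reaches GO:2 along two paths (via GO:3 and GO:5,
  # both children of GO:2)
  dag2 <- go_dag(go_id(1:5),
                 parents = list(character(), "GO:0000001", "GO:0000002",
                                c("GO:0000003", "GO:0000005"), "GO:0000002"))
  sc2 <- c("GO:0000004" = 1)
  # recursive reading counts GO:4 once per path into GO:2 ...
  expect_equal(unname(propagate_scores(sc2, dag2, "sum")["GO:0000002"]), 2)
  # ... the unique-descendant switch counts it once
  expect_equal(
    unname(propagate_scores(sc2, dag2, "sum",
                            unique_descendants = TRUE)["GO:0000002"]), 1)
})

test_that("normalization rescales to max 1 and is idempotent", {
  s <- c("GO:0000002" = 3.5, "GO:0000004" = 2.3, "GO:0000005" = 1.2)
  n <- normalize_scores(s)
  expect_equal(unname(n), c(1, 2.3 / 3.5, 1.2 / 3.5))
  expect_equal(normalize_scores(n), n)
  expect_equal(unname(normalize_scores(c(a = 2, b = 2))), c(1, 1))
  expect_warning(out <- normalize_scores(c(a = 0, b = 0)), "zero")
  expect_length(out, 0)
})

test_that("1NN assigns the nearest neighbor's closed set at confidence 1", {
  dag <- fig9_dag()
  train <- rbind(n1 = c(0, 0), n2 = c(5, 5))
  ann <- list(n1 = "GO:0000004", n2 = "GO:0000006")
  model <- go_knn(train, ann, dag, knn_config(mode = "one_nn"))
  preds <- predict(model, rbind(q1 = c(0.1, 0)))
  expect_setequal(names(preds$q1), c("GO:0000004", "GO:0000002"))
  expect_true(all(preds$q1 == 1))
})

test_that("fixed k=1 with equal weights reproduces the 1NN term set", {
  set.seed(67)
  b <- generate_synthetic_benchmark(synthetic_spec(seed = 7, n_proteins = 20,
                                                   intra_cluster_noise = 1))
  m <- tfpssm_matrix(b$pssms, l = 3)
  pca <- fit_pca(m[b$splits$train, ])
  tr <- pca_transform(pca, m[b$splits$train, ])
  te <- pca_transform(pca, m[b$splits$test, ])
  p1 <- predict(go_knn(tr, b$annotations, b$dag, knn_config("one_nn")), te)
  pk <- predict(go_knn(tr, b$annotations, b$dag,
                       knn_config("fixed", k = 1, weight_scheme = "equal")),
                te)
  expect_setequal(names(p1), names(pk))
  for (q in names(p1)) expect_setequal(names(p1[[q]]), names(pk[[q]]))
})

test_that("dynamic queries with no close neighbor are left unpredicted", {
  dag <- fig9_dag()
  train <- rbind(n1 = c(0, 0), n2 = c(0.1, 0), n3 = c(0, 0.1),
                 n4 = c(0.1, 0.1))
  ann <- list(n1 = "GO:0000004", n2 = "GO:0000004", n3 = "GO:0000005",
              n4 = "GO:0000005")
  model <- go_knn(train, ann, dag, knn_config(mode = "dynamic"))
  preds <- predict(model, rbind(qnear = c(0.05, 0.05), qfar = c(50, 50)))
  expect_true("qnear" %in% names(preds))
  expect_false("qfar" %in% names(preds))
  expect_setequal(attr(preds, "queries"), c("qnear", "qfar"))
  hyb <- predict(go_knn(train, ann, dag, knn_config(mode = "hybrid", k = 2)),
                 rbind(qfar = c(50, 50)))
  expect_true("qfar" %in% names(hyb))
})

test_that("funoverlap weighting excludes zero-overlap neighbors from voting", {
  dag <- fig9_dag()
  train <- rbind(n1 = c(0, 0), n2 = c(0.1, 0))
  ann <- list(n1 = "GO:0000004", n2 = "GO:0000006")
  ff <- list(q = c("F1"), n1 = c("F1", "F2"), n2 = c("F9"))
  model <- go_knn(train, ann, dag,
                  knn_config(mode = "dynamic", weight_scheme = "funoverlap"),
                  funfams = ff)
  # widen threshold manually so both would be neighbors by distance
  model$threshold <- 10
  preds <- predict(model, rbind(q = c(0.05, 0)))
  expect_true("GO:0000004" %in% names(preds$q))   # n1 votes (overlap 1/2)
  expect_false("GO:0000006" %in% names(preds$q))  # n2 excluded (overlap 0)
})

test_that("the naive baseline scores terms by training frequency", {
  dag <- fig9_dag()
  ann <- close_annotations(dag, list(
    a = "GO:0000004", b = "GO:0000004", c = "GO:0000006", d = "GO:0000007"
  ))
  s <- naive_baseline(ann)
  expect_equal(unname(s["GO:0000004"]), 0.5)   # 2 of 4 proteins
  expect_equal(unname(s["GO:0000002"]), 0.5)   # ancestor through closure
  expect_equal(unname(s["GO:0000003"]), 0.5)   # shared ancestor of c and d
  preds <- naive_predict(c("q1", "q2"), ann)
  expect_identical(preds$q1, preds$q2)
  expect_error(naive_baseline(list()), "empty")
})

test_that("the BLAST baseline takes the strongest hit per term and closes sets", {
  dag <- fig9_dag()
  ann <- close_annotations(dag, list(s1 = "GO:0000004", s2 = "GO:0000006"))
  hits <- data.frame(
    query = c("q", "q"), subject = c("s1", "s2"),
    evalue = c(1e-10, 1e-5)
  )
  preds <- blast_baseline(hits, ann)
  s <- preds$q
  expect_equal(unname(s["GO:0000004"]), 1)           # strongest hit
  expect_equal(unname(s["GO:0000006"]), 5 / 10)      # -log10 ratio
  expect_true("GO:0000002" %in% names(s))            # ancestor via closure
  # shared term takes the stronger hit's weight before normalization
  ann2 <- close_annotations(dag, list(s1 = "GO:0000004", s2 = "GO:0000004"))
  s2 <- blast_baseline(hits, ann2)$q
  expect_equal(unname(s2["GO:0000004"]), 1)
  # clamp at 1e-180
  h3 <- data.frame(query = "q", subject = "s1", evalue = 0)
  expect_equal(unname(blast_baseline(h3, ann)$q["GO:0000004"]), 1)
})

test_that("BLAST tabular parsing errors carry the line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  ok <- paste(c("q", "s1", "98.5", "100", "2", "0", "1", "100", "1", "100",
                "1e-50", "190"), collapse = "\t")
  writeLines(c("# comment", ok, "q\ts2\tbroken"), path)
  expect_error(read_blast_hits(path), "line 3")
  writeLines(c(ok), path)
  hits <- read_blast_hits(path)
  expect_equal(hits$evalue, 1e-50)
  expect_equal(hits$subject, "s1")
})

test_that("CAFA-style prediction files round-trip with 2-decimal scores", {
  preds <- structure(
    list(q1 = c("GO:0000004" = 1, "GO:0000002" = 0.657),
         q2 = c("GO:0000006" = 0.004)),
    queries = c("q1", "q2", "q3"), class = "prediction_set"
  )
  path <- withr::local_tempfile(fileext = ".txt")
  write_predictions(preds, path)
  lines <- readLines(path)
  expect_equal(lines[1], "AUTHOR goknn")
  expect_equal(lines[length(lines)], "END")
  back <- read_predictions(path)
  expect_equal(unname(back$q1["GO:0000002"]), 0.66)
  expect_equal(unname(back$q2["GO:0000006"]), 0.01)  # floor at 0.01
})

test_that("knn_config validates mode-dependent fields", {
  expect_error(knn_config(mode = "fixed", k = 0), "positive")
  expect_error(knn_config(mode = "fixed", weight_scheme = "funoverlap"),
               "dynamic")
  expect_s3_class(knn_config("dynamic", weight_scheme = "funoverlap"),
                  "knn_config")
})
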