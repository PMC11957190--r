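write_targets <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("target table: inclusive cutoff, dedup keeps max score", {
  td <- withr::local_tempdir()
  df <- data.frame(mirna = c("m1", "m1", "m2"),
                   gene = c("g1", "g2", "g3"),
                   score = c(79, 80, 85))
  p <- write_targets(df, file.path(td, "t.tsv"))
  tt <- read_target_table(p, score_cutoff = 80)
  expect_equal(nrow(tt), 2)             # 79 excluded, 80 kept (inclusive)
  tt_all <- read_target_table(p, score_cutoff = -Inf)
  expect_equal(nrow(tt_all), 3)

  dup <- data.frame(mirna = c("m1", "m1"), gene = c("g1", "g1"),
                    score = c(82, 90))
  p2 <- write_targets(dup, file.path(td, "d.tsv"))
  tt2 <- read_target_table(p2)
  expect_equal(nrow(tt2), 1)
  expect_equal(tt2$score, 90)

  bad <- data.frame(mirna = c("m1", ""), gene = c("g1", "g2"),
                    score = c(90, 91))
  p3 <- write_targets(bad, file.path(td, "b.tsv"))
  expect_error(read_target_table(p3), "line")
})

test_that("GMT reader: universe union, dedup, degenerate files", {
  td <- withr::local_tempdir()
  p <- file.path(td, "sets.gmt")
  writeLines(c("pw1\tdesc one\tg1\tg2\tg3",
               "pw2\tdesc two\tg3\tg4\tg5\tg6"), p)
  gs <- read_gmt(p)
  expect_equal(length(gs$universe), 6)  # one shared gene
  expect_setequal(gs$sets$pw1, c("g1", "g2", "g3"))

  # duplicated gene within a line stored once
  writeLines("pw\td\tg1\tg1\tg2", p)
  expect_equal(sort(read_gmt(p)$sets$pw), c("g1", "g2"))

  # empty set line skipped with warning; empty file errors
  writeLines(c("ok\td\tg1", "empty\td"), p)
  expect_warning(gs2 <- read_gmt(p), "no genes")
  expect_equal(names(gs2$sets), "ok")
  writeLines(character(), p)
  expect_error(read_gmt(p), "empty GMT")
})

test_that("hypergeometric tail: closed forms and exhaustive enumeration", {
  u <- sprintf("u%02d", 1:20)
  expect_equal(hypergeom_enrich(u[1:5], u[1:5], u),
               1 / choose(20, 5), tolerance = 1e-12)
  # N=10, K=5, n=5, overlap 3 -> 0.5 by enumeration
  u10 <- sprintf("u%02d", 1:10)
  expect_equal(hypergeom_enrich(c(u10[1:3], u10[6:7]), u10[1:5], u10), 0.5)
  # zero overlap: upper tail includes X >= 0, so p = 1
  expect_equal(hypergeom_enrich(u[6:10], u[1:5], u[1:10]),
               1, tolerance = 1e-12)
  expect_error(hypergeom_enrich("a", "b", character()), "empty universe")
  expect_error(hypergeom_enrich("a", "zz", u), "outside the universe")

  # full sweep vs enumeration for all universes up to 12 genes
  for (N in c(5, 8, 12)) {
    uu <- sprintf("g%02d", 1:N)
    for (K in c(2, floor(N / 2))) {
      for (n in c(2, floor(N / 2))) {
        draw <- uu[seq_len(n)]
        pw <- uu[N - K + seq_len(K)]  # arbitrary placement
        k_obs <- length(intersect(draw, pw))
        # relabel so successes are 1..K for the oracle
        p_pkg <- hypergeom_enrich(draw, pw, uu)
        p_or <- oracle_hypergeom(N, K, n, k_obs)
        expect_equal(p_pkg, p_or, tolerance = 1e-12)
      }
    }
  }
})

test_that("enrich_all: planted pathway flagged, edge behaviours", {
  targets <- structure(
    data.frame(mirna = rep(c("m1", "m2"), each = 5),
               gene = sprintf("g%02d", 1:10), score = 90),
    class = c("target_table", "data.frame"))
  # one pathway identical to the pooled target set, universe twice its size
  gs <- list(sets = list(hitpw = sprintf("g%02d", 1:10),
                         other = sprintf("x%02d", 1:10)),
             names = c(hitpw = "planted", other = "background"),
             universe = NULL)
  class(gs) <- "gene_set_collection"
  tab <- enrich_all(c("m1", "m2"), targets, gs)
  expect_equal(tab$pathway_id[1], "hitpw")
  expect_equal(tab$p[1], 1 / choose(20, 10), tolerance = 1e-10)
  expect_true(tab$significant[1])
  expect_false(tab$significant[tab$pathway_id == "other"])
  expect_equal(tab$N[1], 20)

  # hits without targets are an error naming them
  expect_error(enrich_all(c("m1", "mX"), targets, gs), "mX")

  # identical pathways get identical p and q
  gs2 <- gs
  gs2$sets$hitpw2 <- gs$sets$hitpw
  gs2$names <- c(gs2$names, hitpw2 = "copy")
  tab2 <- enrich_all(c("m1", "m2"), targets, gs2)
  expect_equal(tab2$p[tab2$pathway_id == "hitpw"],
               tab2$p[tab2$pathway_id == "hitpw2"])
  expect_equal(tab2$q[tab2$pathway_id == "hitpw"],
               tab2$q[tab2$pathway_id == "hitpw2"])

  # invariant to pathway ordering
  gs3 <- gs
  gs3$sets <- rev(gs3$sets); gs3$names <- rev(gs3$names)
  tab3 <- enrich_all(c("m1", "m2"), targets, gs3)
  expect_equal(tab3[order(tab3$pathway_id), c("p", "q")],
               tab[order(tab$pathway_id), c("p", "q")])
})

test_that("synthetic target generator produces an enrichable structure", {
  ids <- sprintf("mir_%04d", 1:40)
  td <- gen_target_data(ids, signal_mirnas = ids[1:8], seed = 2)
  expect_true(all(c("mirna", "gene", "score") %in% names(td$targets)))
  tt <- filter_target_table(td$targets, 80)
  expect_true(all(tt$score >= 80))
  tmp <- withr::local_tempdir()
  gmt <- file.path(tmp, "p.gmt")
  writeLines(td$gmt_lines, gmt)
  gs <- read_gmt(gmt)
  usable <- intersect(ids[1:8], tt$mirna)
  tab <- enrich_all(usable, tt, gs)
  # the signal block is pathway_01 and should rank first
  expect_equal(tab$pathway_id[1], "pathway_01")
  expect_true(tab$significant[1])
})
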