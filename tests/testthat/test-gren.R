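test_that("dedup merges overlapping enhancers and resolves classes", {
  # identical region carrying a C pair and an H pair -> one CH region
  pairs <- dplyr::bind_rows(
    pair_row("G1", 0, 1000, "CLL", "C"),
    pair_row("G1", 0, 1000, "NBC", "H"),
    pair_row("G2", 5000, 6000, "CLL", "C")
  )
  got <- dedup_enhancers(pairs)
  expect_equal(nrow(got$enhancers), 2)
  expect_equal(got$enhancers$class[got$enhancers$start == 0], "CH")
  expect_equal(got$enhancers$class[got$enhancers$start == 5000], "C")
  # disjoint regions unchanged; overlapping ones merged to the union
  pairs2 <- dplyr::bind_rows(
    pair_row("G1", 0, 1000, "CLL", "C"),
    pair_row("G2", 500, 1500, "CLL", "C")
  )
  got2 <- dedup_enhancers(pairs2)
  expect_equal(as.data.frame(got2$enhancers[, c("start", "end")]),
               data.frame(start = 0L, end = 1500L))
  expect_true(all(got2$pairs$e_start == 0 & got2$pairs$e_end == 1500))
  # merging is idempotent: re-running on the remapped pairs changes nothing
  again <- dedup_enhancers(got2$pairs)
  expect_equal(again$enhancers, got2$enhancers)
  # promoters without a gene mapping are dropped with a count
  map <- c(G1 = "TP53")
  expect_message(got3 <- dedup_enhancers(pairs2, gene_map = map), "1 pair")
  expect_equal(unique(got3$pairs$gene), "TP53")
})

test_that("enhancer numbering is genomic, per class, and order-invariant", {
  enh <- tibble::tibble(chrom = "chr1", start = c(900, 100, 500),
                        end = c(1000, 200, 600), class = "C")
  got <- number_enhancers(enh)
  expect_equal(got$enhancer_id, c("C1", "C2", "C3"))
  expect_equal(got$start, c(100, 500, 900))
  expect_equal(number_enhancers(enh[c(3, 1, 2), ]), got)
  # classes are numbered independently
  mixed <- tibble::tibble(chrom = "chr1",
                          start = c(100, 200, 300, 400),
                          end = c(150, 250, 350, 450),
                          class = c("C", "H", "C", "CH"))
  gm <- number_enhancers(mixed)
  expect_equal(gm$enhancer_id, c("C1", "H1", "C2", "CH1"))
})

test_that("differential selections apply the strict thresholds", {
  tbl <- tibble::tibble(regulator = paste0("R", 1:3),
                        p = c(0.001, 0.02, 0.9),
                        padj = c(0.049, 0.05, 0.9))
  expect_equal(select_differential_regulators(tbl), "R1")
  # BH applied when padj is absent; matches the step-up rule computed by hand
  p <- c(0.001, 0.008, 0.039, 0.041, 0.6)
  bh_manual <- {
    n <- length(p); o <- order(p)
    adj <- p[o] * n / seq_len(n)
    cummin(rev(adj)) |> rev() |> pmin(1) |> (\(x) x[order(o)])()
  }
  tbl2 <- tibble::tibble(regulator = paste0("R", 1:5), p = p)
  expect_equal(select_differential_regulators(tbl2),
               paste0("R", which(bh_manual < 0.05)))

  de <- tibble::tibble(gene = c("A", "B", "C"),
                       p = c(0.005, 0.005, 0.02),
                       lfc = c(1.8, 1.7, 3))
  expect_equal(select_deregulated_genes(de), "A")  # 1.7 and p=0.02 both fail
})

test_that("assembly integrates enhancers and drops unknown genes", {
  t <- toy_gren()
  expect_message(
    g <- assemble_gren(t$edges, t$numbered, t$pairs,
                       modifier_list = "GC"),
    "dropped")
  gl <- glance(g)
  expect_equal(gl$n_regulators, 2)
  expect_equal(gl$n_targets, 3)      # GA, GB, GC
  expect_equal(gl$n_enhancers, 2)    # GX enhancer dropped as dangling
  expect_equal(gl$n_modifiers, 1)
  expect_equal(gl$n_edges, 4 + 2)
  # every enhancer node keeps at least one gene edge and carries coordinates
  enh_nodes <- g$nodes[g$nodes$type == "enhancer", ]
  expect_true(all(enh_nodes$name %in% g$edges$from[g$edges$kind == "enhances"]))
  expect_false(any(is.na(enh_nodes$start)))
  # empty pair list: a plain regulator-target network
  g0 <- assemble_gren(t$edges)
  expect_equal(glance(g0)$n_enhancers, 0)
})

test_that("the disease subnetwork is the documented induced subgraph", {
  t <- toy_gren()
  suppressMessages(g <- assemble_gren(t$edges, t$numbered, t$pairs))
  sub <- extract_disease_subnetwork(g, core_tfs = "TF1",
                                    deregulated_genes = "GA")
  expect_setequal(sub$nodes$name,
                  c("TF1", "GA", g$nodes$name[g$nodes$class %in% "C" &
                                                g$nodes$type == "enhancer"]))
  # edges are a subset of the parent graph
  key <- function(e) paste(e$from, e$to)
  expect_true(all(key(sub$edges) %in% key(g$edges)))
  # a core TF with no deregulated targets is retained, isolated
  sub2 <- extract_disease_subnetwork(g, core_tfs = "TF2",
                                     deregulated_genes = character())
  expect_equal(sub2$nodes$name, "TF2")
  expect_equal(nrow(sub2$edges), 0)
  # enlarging the core never removes nodes
  sub3 <- extract_disease_subnetwork(g, core_tfs = c("TF1", "TF2"),
                                     deregulated_genes = "GA")
  expect_true(all(sub$nodes$name %in% sub3$nodes$name))
  # unknown core TFs are warned about and skipped
  expect_warning(extract_disease_subnetwork(g, core_tfs = c("TF1", "NOPE"),
                                            deregulated_genes = "GA"),
                 "NOPE")
})

test_that("GREN serialization round-trips exactly and converts to igraph", {
  t <- toy_gren()
  suppressMessages(g <- assemble_gren(t$edges, t$numbered, t$pairs,
                                      modifier_list = "GC"))
  d <- withr::local_tempdir()
  write_gren(g, d)
  g2 <- read_gren(d)
  expect_identical(g2$nodes, g$nodes)
  expect_identical(g2$edges, g$edges)
  ig <- as_igraph(g)
  expect_equal(igraph::vcount(ig), nrow(g$nodes))
  expect_equal(igraph::ecount(ig), nrow(g$edges))
  expect_setequal(igraph::V(ig)$type, unique(g$nodes$type))
})
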