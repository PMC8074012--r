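test_that("directional overlap handles same, opposite and gene-level modes", {
  x <- gl("x", up = "g")
  y_same <- gl("y", up = "g")
  y_opp <- gl("y", down = "g")

  expect_identical(entries_of(directional_overlap(x, y_same, "same")),
                   tibble::tibble(gene = "g", direction = "induced"))
  expect_identical(nrow(directional_overlap(x, y_opp, "same")), 0L)
  opp <- directional_overlap(x, y_opp, "opposite")
  expect_identical(entries_of(opp),
                   tibble::tibble(gene = "g", direction = "induced"))
  opp_y <- directional_overlap(x, y_opp, "opposite", keep = "y")
  expect_identical(entries_of(opp_y),
                   tibble::tibble(gene = "g", direction = "repressed"))
  z <- gl("z", up = "other")
  for (m in c("same", "opposite", "any")) {
    expect_identical(nrow(directional_overlap(x, z, m)), 0L)
  }
})

test_that("list A keeps dual-direction genes under both directions", {
  merged <- gene_list(tibble::tibble(
    gene = c("g1", "g2", "g2"),
    direction = c("induced", "induced", "repressed"),
    splice_conflict = c(FALSE, TRUE, TRUE)), name = "mg")
  a <- build_list_a(merged)
  expect_identical(list_name(a), "A")
  expect_identical(nrow(a), 3L)
  expect_setequal(a$direction[a$gene == "g2"], c("induced", "repressed"))
  expect_identical(nrow(build_list_a(gene_list(name = "mg"))), 0L)
})

test_that("A1 is the same-direction overlap and a subset of both parents", {
  l1 <- gl("1", up = c("a", "b"), down = "c")
  l2 <- gl("2", up = "a", down = c("b", "d"))
  a1 <- build_list_a1(l1, l2)
  expect_identical(entries_of(a1),
                   tibble::tibble(gene = "a", direction = "induced"))
  expect_true(all(a1$gene %in% l1$gene))
  expect_true(all(a1$gene %in% l2$gene))
})

test_that("B1 collects combined-only, sign-flip and one-color routes minus A1 and list 11", {
  l1 <- gl("1", up = "shared", down = "flip")
  l2 <- gl("2", up = c("only2", "shared", "flip"))
  l3 <- gl("3", up = "in3")
  l7 <- gl("7", up = c("oc", "in3"))
  a1 <- build_list_a1(l1, l2)
  l11 <- directional_overlap(l3, l7, "same")
  b1 <- build_list_b1(l2, l3, l1, l7, a1, l11)
  tb <- entries_of(b1)
  # only2: in 2 but not 3 -> in; flip: opposite in 1 and 2 -> in;
  # oc: one-color call -> in; shared: in A1 -> out; in3: in list 11 -> out
  expect_setequal(tb$gene, c("only2", "flip", "oc"))
  expect_true(all(tb$direction == "induced"))
})

test_that("B2 holds reversals under the treatment-modulation direction", {
  l2 <- gl("2", down = "rev")
  l3 <- gl("3", up = c("rev", "equiv", "kept"))
  a1 <- gl("A1")
  b2 <- build_list_b2(l2, l3, equiv_genes = "equiv", a1 = a1)
  tb <- entries_of(b2)
  expect_setequal(tb$gene, c("rev", "equiv"))
  # direction is opposite to the insult direction
  expect_true(all(tb$direction == "repressed"))
  # A1 genes are excluded
  b2b <- build_list_b2(l2, l3, equiv_genes = "equiv",
                       a1 = gl("A1", up = "rev"))
  expect_setequal(entries_of(b2b)$gene, "equiv")
})

test_that("the amplification criterion splits list 11 into B3 and C exactly", {
  l2 <- gl("2", up = "amp")
  l3 <- gl("3", up = c("amp", "ins"), down = "mixed")
  l7 <- gl("7", up = c("amp", "ins", "lone"), down = "mixed")
  a1 <- gl("A1")
  b3 <- build_list_b3(l3, l7, l2, a1)
  cl <- build_list_c(l3, l7, l2)
  expect_identical(entries_of(b3),
                   tibble::tibble(gene = "amp", direction = "induced"))
  expect_setequal(entries_of(cl)$gene, c("ins", "mixed"))
  # lone is only in the one-color list: in neither B3 nor C
  expect_false("lone" %in% c(b3$gene, cl$gene))
  # partition: B3 and C are disjoint and their union is list 11
  l11 <- directional_overlap(l3, l7, "same")
  expect_identical(nrow(dplyr::inner_join(entries_of(b3), entries_of(cl),
                                          by = c("gene", "direction"))), 0L)
  expect_identical(dplyr::arrange(dplyr::bind_rows(entries_of(b3),
                                                   entries_of(cl)), gene),
                   dplyr::arrange(entries_of(l11), gene))
})

test_that("assembling B records provenance and rejects overlapping sub-lists", {
  b <- build_list_b(gl("B1", up = "g1"), gl("B2", down = "g2"),
                    gl("B3", up = "g3"))
  expect_identical(nrow(b), 3L)
  expect_setequal(b$provenance, c("B1", "B2", "B3"))
  expect_identical(nrow(build_list_b(gl("B1"), gl("B2"), gl("B3"))), 0L)
  expect_error(build_list_b(gl("B1", up = "dup"), gl("B2", up = "dup"),
                            gl("B3")),
               "dup")
})

test_that("classification assigns one category per entry with provenance", {
  lists <- list(A = gl("A", up = c("mg", "sh")),
                A1 = gl("A1", up = "sh"),
                B1 = gl("B1", up = "dn"),
                B2 = gl("B2", down = "rv"),
                B3 = gl("B3", up = "am"),
                C = gl("C", up = "in"))
  cls <- classify_genes(lists, genes = c("mg", "sh", "dn", "rv", "am", "in",
                                         "nothing"))
  get <- function(g) cls$category[cls$gene == g]
  expect_identical(get("mg"), "mg_only")
  expect_identical(get("sh"), "shared")
  expect_identical(get("dn"), "de_novo")
  expect_identical(get("rv"), "reversed")
  expect_identical(get("am"), "amplified")
  expect_identical(get("in"), "insensitive")
  expect_identical(get("nothing"), "unaffected")
  expect_identical(cls$provenance[cls$gene == "sh"], "A+A1")
  expect_error(classify_genes(list(A = gl("A"), A1 = gl("A1"),
                                   B1 = gl("B1", up = "x"),
                                   B2 = gl("B2", up = "x"),
                                   B3 = gl("B3"), C = gl("C"))),
               "contradictory")
})

test_that("venn counts equal brute-force enumeration on random lists", {
  pool <- sprintf("g%02d", 1:30)
  set.seed(42)
  for (i in 1:10) {
    lists <- list(one = random_list("one", pool),
                  two = random_list("two", pool),
                  three = random_list("three", pool))
    vc <- venn_counts(lists)
    sets <- lapply(lists, list_genes)
    for (j in seq_len(nrow(vc))) {
      nm <- strsplit(vc$lists[j], "&", fixed = TRUE)[[1]]
      expected <- sum(vapply(pool, function(g) {
        all(vapply(nm, function(s) g %in% sets[[s]], logical(1)))
      }, logical(1)))
      expect_identical(vc$n_genes[j], expected)
    }
  }
  # degenerate cases
  same <- gl("s", up = "g")
  vc <- venn_counts(list(a = same, b = same, c = same))
  expect_true(all(vc$n_genes == 1L))
})

test_that("algebra invariants hold over random directional inputs", {
  pool <- sprintf("g%02d", 1:40)
  set.seed(99)
  for (i in 1:15) {
    l1 <- random_list("mg", pool)
    l2 <- random_list("mghi_hi", pool)
    l3 <- random_list("hi", pool)
    l7 <- random_list("mghi_ctrl", pool)
    equiv <- pool[stats::runif(40) < 0.2]
    ls <- interaction_lists(l1, l2, l3, l7, equiv_genes = equiv)

    # A1 subset of both parents, gene-level
    expect_true(all(ls$A1$gene %in% l1$gene))
    expect_true(all(ls$A1$gene %in% l2$gene))
    # subtraction invariants
    expect_identical(length(intersect(ls$B1$gene, ls$A1$gene)), 0L)
    expect_identical(length(intersect(ls$B2$gene, ls$A1$gene)), 0L)
    expect_identical(length(intersect(ls$B3$gene, ls$A1$gene)), 0L)
    l11 <- directional_overlap(l3, l7, "same")
    expect_identical(nrow(dplyr::inner_join(entries_of(ls$B1),
                                            entries_of(l11),
                                            by = c("gene", "direction"))), 0L)
    # B sub-lists pairwise disjoint as entries
    subs <- list(entries_of(ls$B1), entries_of(ls$B2), entries_of(ls$B3))
    for (p in 1:2) for (q in (p + 1):3) {
      expect_identical(nrow(dplyr::inner_join(subs[[p]], subs[[q]],
                                              by = c("gene", "direction"))),
                       0L)
    }
    # B3 and C partition list 11 up to A1 removals
    l10 <- directional_overlap(l11, l2, "same")
    expected <- dplyr::anti_join(
      entries_of(l11),
      entries_of(l10)[entries_of(l10)$gene %in% ls$A1$gene, ],
      by = c("gene", "direction"))
    got <- dplyr::bind_rows(entries_of(ls$B3), entries_of(ls$C))
    expect_identical(dplyr::arrange(got, gene, direction),
                     dplyr::arrange(expected, gene, direction))
  }
})
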