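test_that("gene status resolves synonyms with present > pseudo > absent", {
  expect_equal(gene_status("lacZ", character(0), c("lacZ", "lacLM")), "present")
  expect_equal(gene_status(character(0), "lacZ", c("lacZ", "lacLM")), "pseudo")
  expect_equal(gene_status("xyz", "abc", c("lacZ", "lacLM")), "absent")
  expect_error(gene_status("x", "y", character(0)), "non-empty")
})

test_that("pathway completeness equals exhaustive boolean evaluation", {
  states <- c("present", "pseudo", "absent")
  def <- pathway_def("toy", list(
    list(genes = c("t1", "t2"), transporter = TRUE),
    list(genes = "e1"),
    list(genes = c("e2", "e3"))))
  genes <- c("t1", "t2", "e1", "e2", "e3")
  combos <- expand.grid(rep(list(states), 5), stringsAsFactors = FALSE)
  names(combos) <- genes
  for (r in seq_len(nrow(combos))) {
    st <- data.frame(strain_id = "s", gene_id = genes,
                     status = unlist(combos[r, ]), stringsAsFactors = FALSE)
    got <- pathway_complete(def, st, "s")
    expected <- (combos[r, "t1"] == "present" || combos[r, "t2"] == "present") &&
      combos[r, "e1"] == "present" &&
      (combos[r, "e2"] == "present" || combos[r, "e3"] == "present")
    expect_equal(got$complete, expected)
    if (!expected) {
      # failing-group classes: fragmentation iff a pseudo member exists
      for (k in seq_len(nrow(got$failing))) {
        g <- def$groups[[got$failing$group[k]]]$genes
        cls <- if (any(combos[r, g] == "pseudo")) "fragmentation" else "absence"
        expect_equal(got$failing$class[k], cls)
      }
    }
  }
  expect_error(pathway_def("bad", list()), "at least one")
  expect_error(pathway_def("bad", list(list(genes = character(0)))), "empty")
})

test_that("phenotype prediction follows pathway completeness", {
  defs <- list(
    S1 = pathway_def("S1", list(list(genes = "tA", transporter = TRUE),
                                list(genes = "eA"))),
    S2 = pathway_def("S2", list(list(genes = "tB", transporter = TRUE),
                                list(genes = "eB"))))
  st_all <- data.frame(strain_id = "x", gene_id = c("tA", "eA", "tB", "eB"),
                       status = "present")
  expect_true(all(predict_phenotypes(defs, st_all) == "+"))
  st_ko <- st_all; st_ko$status[st_ko$gene_id == "tB"] <- "absent"
  p <- predict_phenotypes(defs, st_ko)
  expect_equal(unname(p["x", ]), c("+", "-"))
  st_none <- data.frame(strain_id = "x", gene_id = "zz", status = "present")
  expect_true(all(predict_phenotypes(defs, st_none) == "-"))
  # substrate without definition is untested
  p2 <- predict_phenotypes(defs["S1"], st_all, substrates = c("S1", "S9"))
  expect_equal(unname(p2["x", "S9"]), "untested")
})

test_that("shipped pathway definitions parse into 14 substrate models", {
  defs <- read_pathway_defs(system.file("extdata", "pathway_defs.yaml",
                                        package = "reducto"))
  expect_length(defs, 14)
  expect_true(all(vapply(defs, inherits, logical(1), "pathway_def")))
  expect_true("Lactose" %in% names(defs))
  expect_true(any(vapply(defs$Lactose$groups, `[[`, logical(1), "transporter")))
})

test_that("discriminating substrates equal a brute-force per-column scan", {
  set.seed(1)
  meta <- setNames(rep(c("lactis", "bulgaricus"), each = 4), paste0("s", 1:8))
  for (r in 1:10) {
    m <- matrix(sample(c("+", "-", "untested"), 8 * 10, TRUE,
                       prob = c(.45, .45, .1)),
                8, 10, dimnames = list(paste0("s", 1:8), paste0("sub", 1:10)))
    got <- compare_and_discriminate(m, meta)$discriminating
    exp_d <- character(0)
    for (s in colnames(m)) {
      a <- m[1:4, s]; a <- a[a != "untested"]
      b <- m[5:8, s]; b <- b[b != "untested"]
      if (length(a) && length(b) &&
          ((all(a == "+") && all(b == "-")) ||
           (all(a == "-") && all(b == "+")))) {
        exp_d <- c(exp_d, s)
      }
    }
    expect_setequal(got, exp_d)
  }
  # identical subspecies profiles: nothing discriminates
  m2 <- matrix("+", 4, 3, dimnames = list(paste0("s", c(1, 2, 5, 6)), NULL))
  expect_length(compare_and_discriminate(m2, meta)$discriminating, 0)
})

test_that("adding a strain can only shrink or preserve the discriminating set", {
  set.seed(2)
  meta <- setNames(rep(c("lactis", "bulgaricus"), each = 5), paste0("s", 1:10))
  for (r in 1:10) {
    m <- matrix(sample(c("+", "-"), 10 * 8, TRUE), 10, 8,
                dimnames = list(paste0("s", 1:10), paste0("sub", 1:8)))
    d_small <- compare_and_discriminate(m[c(1:4, 6:9), ], meta)$discriminating
    d_full <- compare_and_discriminate(m, meta)$discriminating
    expect_true(all(d_full %in% d_small))
  }
})

test_that("fermented-substrate counts are row sums of '+'", {
  ph <- read_phenotype_table(table3_path())
  cmp <- compare_and_discriminate(ph$matrix, ph$meta)
  expect_equal(unname(cmp$counts), unname(rowSums(ph$matrix == "+")))
  # concordance against an identical prediction is 1
  cmp2 <- compare_and_discriminate(ph$matrix, ph$meta, predicted = ph$matrix)
  expect_equal(cmp2$concordance, 1)
})
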