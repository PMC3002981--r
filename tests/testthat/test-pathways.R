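test_that("ratio classification follows the legend semantics", {
  m <- matrix(c(0.00001, 0.55, 1.0, 1.6, 0.7, 0.02, 0.6, 1.5), 1,
              dimnames = list("mut", paste0("a", 1:8)))
  cls <- classify_ratios(m)
  expect_equal(unname(unclass(cls)[1, ]),
               c("undetectable", "decreased", "unchanged", "increased",
                 "unchanged",
                 "decreased",    # 0.02 is not < 0.02: milder label
                 "unchanged",    # 0.6 is not < 0.6
                 "unchanged"))   # 1.5 is not > 1.5

  expect_error(classify_ratios(matrix(-1, 1, 1)), "negative ratio")
  expect_error(classify_ratios(m, thresholds = c(undetectable = 0.7,
                                                 decreased = 0.6,
                                                 increased = 1.5)),
               "thresholds")
})

test_that("classification is idempotent, total, and matches a histogram oracle", {
  set.seed(41)
  m <- matrix(rexp(60, rate = 1), 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("a", 1:10)))
  cls <- unclass(classify_ratios(m))
  expect_false(any(is.na(cls)))
  # brute-force per-cell label oracle
  oracle <- vapply(as.vector(m), function(r) {
    if (r < 0.02) "undetectable" else if (r < 0.6) "decreased"
    else if (r > 1.5) "increased" else "unchanged"
  }, character(1))
  expect_equal(as.vector(cls), oracle)
  expect_equal(c(table(as.vector(cls))), c(table(oracle)))
})

test_that("enzyme-product inference flags abolished and reduced products", {
  m <- matrix(1, 2, 3, dimnames = list(c("tad1", "wtish"),
                                       c("m1I", "I", "yW")))
  m["tad1", "m1I"] <- 0.00001
  m["tad1", "I"] <- 0.4
  sig <- matrix(TRUE, 2, 3, dimnames = dimnames(m))
  links <- infer_enzyme_products(classify_ratios(m), m, sig)
  expect_equal(links$strain[1], "tad1")
  expect_equal(links$short_name[1], "m1I")
  expect_equal(links$strength[1], "abolished")
  expect_equal(links$strength[links$short_name == "I"], "reduced")

  ones <- matrix(1, 3, 3, dimnames = list(paste0("s", 1:3), paste0("a", 1:3)))
  sig1 <- ones == 1
  expect_equal(nrow(infer_enzyme_products(classify_ratios(ones), ones, sig1)),
               0L)
})

test_that("inference equals a brute-force filter and is permutation-stable", {
  set.seed(42)
  m <- matrix(rexp(40), 5, 8,
              dimnames = list(paste0("s", 1:5), paste0("a", 1:8)))
  sig <- matrix(runif(40) < 0.7, 5, 8, dimnames = dimnames(m))
  links <- infer_enzyme_products(classify_ratios(m), m, sig)
  # exhaustive cell scan
  brute <- list()
  for (i in 1:5) for (j in 1:8) {
    r <- m[i, j]
    if (!sig[i, j]) next
    if (r < 0.02) brute[[length(brute) + 1]] <-
        data.frame(strain = rownames(m)[i], short_name = colnames(m)[j],
                   ratio = r, strength = "abolished")
    else if (r < 0.6) brute[[length(brute) + 1]] <-
        data.frame(strain = rownames(m)[i], short_name = colnames(m)[j],
                   ratio = r, strength = "reduced")
  }
  brute <- do.call(rbind, brute)
  brute <- brute[order(brute$ratio, brute$strain, brute$short_name), ]
  rownames(brute) <- NULL
  expect_equal(links, brute)

  rp <- sample(5); cp <- sample(8)
  links2 <- infer_enzyme_products(classify_ratios(m[rp, cp]), m[rp, cp],
                                  sig[rp, cp])
  expect_equal(links2, links)
})

test_that("ungated inference warns when significance flags are absent", {
  m <- matrix(c(0.5, 1), 1, 2, dimnames = list("s", c("a", "b")))
  expect_warning(infer_enzyme_products(classify_ratios(m), m), "ungated")
})

test_that("redundancy candidates are tiered and ranked by correlation", {
  set.seed(43)
  base <- rnorm(10)
  m <- rbind(twin1 = base + rnorm(10, 0, 1e-9), twin2 = base,
             other = rnorm(10))
  cm <- profile_correlation(m)
  red <- redundancy_candidates(cm)
  expect_equal(sort(unlist(red[1, c("strain1", "strain2")],
                           use.names = FALSE)),
               c("twin1", "twin2"))
  expect_equal(red$tier[1], "strong")

  # brute-force enumeration over all pairs of a random 5-strain matrix
  m5 <- matrix(rnorm(50), 5, 10, dimnames = list(paste0("s", 1:5), NULL))
  cm5 <- profile_correlation(m5)
  red5 <- redundancy_candidates(cm5, strong = 0.3, weak = -0.2)
  brute <- list()
  for (i in 1:4) for (j in (i + 1):5) {
    cc <- cor(m5[i, ], m5[j, ])
    if (cc > -0.2) brute[[length(brute) + 1]] <-
        data.frame(strain1 = paste0("s", i), strain2 = paste0("s", j),
                   correlation = cc,
                   tier = if (cc > 0.3) "strong" else "moderate")
  }
  brute <- do.call(rbind, brute)
  brute <- brute[order(-brute$correlation), ]
  rownames(brute) <- NULL
  expect_equal(red5, brute, tolerance = 1e-12)

  # independent noise profiles: no pair exceeds the default thresholds
  set.seed(44)
  noise <- matrix(rnorm(4 * 500), 4, 500,
                  dimnames = list(paste0("n", 1:4), NULL))
  expect_equal(nrow(redundancy_candidates(profile_correlation(noise))), 0L)
})

test_that("gene-dosage check accepts ~half-level heterozygotes", {
  expect_true(gene_dosage_check(0.6)$consistent)    # ~40% reduction
  expect_false(gene_dosage_check(1.0)$consistent)
  expect_true(gene_dosage_check(0.5, tolerance = 0)$consistent)
})

test_that("the shipped position annotation covers every analyte", {
  reg <- default_registry()
  pos <- modification_positions()
  expect_setequal(pos$short_name, analyte_names(reg))
})
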