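two_class_bits <- function(bits_a, bits_b, fragment = "subfp_x") {
  n <- length(bits_a) + length(bits_b)
  desc <- tibble::tibble(
    compound_id = sprintf("c%02d", seq_len(n)))
  desc[[fragment]] <- c(bits_a, bits_b)
  classes <- tibble::tibble(
    compound_id = desc$compound_id,
    target_class = c(rep("wild", length(bits_a)),
                     rep("mutant", length(bits_b))))
  list(desc = desc, classes = classes)
}

test_that("fragment frequency matches its worked examples", {
  # present everywhere: class prevalence equals overall prevalence
  d <- two_class_bits(rep(1, 5), rep(1, 5))
  expect_equal(fragment_frequency(d$desc, d$classes, "subfp_x", "wild")$frequency, 1.0)

  # absent from the class
  d <- two_class_bits(rep(0, 5), rep(1, 5))
  expect_equal(fragment_frequency(d$desc, d$classes, "subfp_x", "wild")$frequency, 0.0)

  # all of class A (5/5), none of B: (5/5)/(5/10) = 2
  d <- two_class_bits(rep(1, 5), rep(0, 5))
  rec <- fragment_frequency(d$desc, d$classes, "subfp_x", "wild")
  expect_equal(rec$frequency, 2.0)
  expect_equal(rec$N_fragment_class, 5)
  expect_equal(rec$N_fragment_total, 5)
  expect_equal(rec$N_total, 10)
})

test_that("fragment frequency validates its inputs", {
  d <- two_class_bits(rep(1, 3), rep(0, 3))
  d$desc$subfp_x[1] <- 0.5
  expect_error(fragment_frequency(d$desc, d$classes, "subfp_x", "wild"),
               "binary")
  d <- two_class_bits(rep(1, 3), rep(0, 3))
  expect_error(fragment_frequency(d$desc, d$classes, "subfp_x", "other"),
               "empty or unknown")
  one_class <- d$classes |> dplyr::mutate(target_class = "wild")
  expect_error(fragment_frequency(d$desc, one_class, "subfp_x", "wild"),
               "two classes")
})

test_that("class-weighted frequencies sum to one for any present fragment", {
  for (i in 1:20) {
    dat <- withr::with_seed(500 + i, {
      na <- sample(4:20, 1); nb <- sample(4:20, 1)
      two_class_bits(rbinom(na, 1, runif(1)), rbinom(nb, 1, runif(1)))
    })
    tab <- fragment_frequency_table(dat$desc, dat$classes)
    if (tab$N_fragment_total[1] == 0) next
    weighted <- sum((tab$N_class / tab$N_total) * tab$frequency)
    expect_equal(weighted, 1, tolerance = 1e-12)
  }
})

test_that("exclusive fragments have frequency N_total/N_class in their class", {
  d <- two_class_bits(rep(1, 6), rep(0, 4))
  rec <- fragment_frequency(d$desc, d$classes, "subfp_x", "wild")
  expect_equal(rec$frequency, 10 / 6)
  expect_equal(fragment_frequency(d$desc, d$classes, "subfp_x",
                                  "mutant")$frequency, 0)
})

test_that("strict and relaxed exclusivity thresholds behave as documented", {
  # planted: all of mutant, none of wild
  d <- two_class_bits(rep(0, 10), rep(1, 10))
  ex <- find_exclusive_fragments(d$desc, d$classes)
  expect_equal(ex$class[ex$rule == "strict"], "mutant")

  # one wild molecule carries it: not strict, but relaxed at 0.9/0.1
  d2 <- two_class_bits(c(1, rep(0, 9)), rep(1, 10))
  ex2 <- find_exclusive_fragments(d2$desc, d2$classes)
  expect_false("strict" %in% ex2$rule)
  expect_equal(ex2$class[ex2$rule == "relaxed"], "mutant")

  # no class-pure bits at all
  d3 <- two_class_bits(c(1, 1, 0, 0, 1), c(1, 0, 1, 0, 1))
  expect_equal(nrow(find_exclusive_fragments(d3$desc, d3$classes) |>
                      dplyr::filter(rule == "strict")), 0)
})

test_that("common fragments respect the joint prevalence threshold", {
  d <- two_class_bits(rep(1, 8), rep(1, 6))
  expect_equal(find_common_fragments(d$desc, d$classes, 1.0)$fragment_id,
               "subfp_x")

  d2 <- two_class_bits(c(rep(1, 5), rep(0, 5)), c(rep(1, 9), 0))
  expect_equal(nrow(find_common_fragments(d2$desc, d2$classes, 0.8)), 0)
})

test_that("threshold 1.0 equals the brute-force all-present intersection", {
  dat <- withr::with_seed(42, {
    n <- 20
    desc <- tibble::tibble(compound_id = sprintf("c%02d", 1:n))
    for (j in 1:12) desc[[sprintf("subfp_b%02d", j)]] <- rbinom(n, 1, 0.8)
    classes <- tibble::tibble(compound_id = desc$compound_id,
                              target_class = rep(c("wild", "mutant"), 10))
    list(desc = desc, classes = classes)
  })
  got <- find_common_fragments(dat$desc, dat$classes, 1.0)$fragment_id
  m <- as.matrix(dat$desc[-1])
  cl <- dat$classes$target_class
  brute <- colnames(m)[colSums(m[cl == "wild", ]) == sum(cl == "wild") &
                       colSums(m[cl == "mutant", ]) == sum(cl == "mutant")]
  expect_setequal(got, brute)
})

test_that("fragment enrichment plots build without error", {
  dat <- withr::with_seed(55, {
    desc <- tibble::tibble(compound_id = sprintf("c%02d", 1:16))
    for (j in 1:6) desc[[sprintf("subfp_b%d", j)]] <- rbinom(16, 1, 0.5)
    classes <- tibble::tibble(compound_id = desc$compound_id,
                              target_class = rep(c("wild", "mutant"), 8))
    list(desc = desc, classes = classes)
  })
  tab <- fragment_frequency_table(dat$desc, dat$classes)
  expect_s3_class(plot_fragment_enrichment(tab, top_n = 4), "ggplot")
})

test_that("the two-scaffold generator yields class-pure scaffold fragments", {
  d <- cached("fragment_two_regime", {
    tr <- make_two_regime_dataset(
      synth_config(n = 12, seed = 31),
      synth_config(n = 12, scaffold = "pyrazolopyrimidine",
                   class_label = "mutant", seed = 32))
    tr$descriptors <- compute_descriptors(
      tr$compounds, families = c("substructure_fp", "maccs_like_fp"))
    tr
  })
  ex <- find_exclusive_fragments(d$descriptors, d$compounds)
  strict <- ex |> dplyr::filter(rule == "strict")
  # the azole key marks the pyrazolopyrimidine scaffold only
  expect_true("subfp_azole" %in% strict$fragment_id[strict$class == "mutant"])
  tab <- fragment_frequency_table(d$descriptors, d$compounds)
  azole <- tab |> dplyr::filter(fragment_id == "subfp_azole")
  expect_equal(azole$frequency[azole$class == "mutant"], 2)
  expect_equal(azole$frequency[azole$class == "wild"], 0)
})
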