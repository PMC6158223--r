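test_that("wormwiring-dialect parsing separates chemical and electrical rows", {
  cx <- read_connectome_table(ww_fixture_csv(), "wormwiring")
  expect_s3_class(cx, "connectome")
  expect_equal(nrow(cx$cells), 4)
  expect_setequal(cx$cells$name, c("AVBL", "DB1", "DD1", "MDL08"))
  expect_equal(nrow(cx$chemical), 2)
  expect_equal(nrow(cx$electrical), 1)
  expect_equal(cx$electrical$n_contacts, 2L)
  chem <- cx$chemical[order(cx$chemical$pre), ]
  expect_equal(chem$pre, c("DB1", "DD1"))
  expect_equal(chem$n_contacts, c(5L, 3L))
  expect_equal(chem$neurotransmitter, c("Acetylcholine", "GABA"))
})

test_that("a header-only table yields an empty connectome", {
  cx <- read_connectome_table(
    "Origin,Target,Type,Number of Connections,Neurotransmitter", "wormwiring")
  expect_equal(nrow(cx$cells), 0)
  expect_equal(nrow(cx$chemical), 0)
  expect_equal(nrow(cx$electrical), 0)
})

test_that("reader errors name the offending column or row", {
  expect_error(read_connectome_table("Origin,Target,Type\nA,B,Send", "wormwiring"),
               "Number of Connections")
  bad_count <- c("Origin,Target,Type,Number of Connections,Neurotransmitter",
                 "A,B,Send,0,ACh")
  expect_error(read_connectome_table(bad_count, "wormwiring"), "row 1")
  frac <- c("Origin,Target,Type,Number of Connections,Neurotransmitter",
            "A,B,Send,2.5,ACh")
  expect_error(read_connectome_table(frac, "wormwiring"), "integer")
})

test_that("varshney dialect handles S/Sp/R/Rp/EJ/NMJ types", {
  csv <- c("Neuron 1,Neuron 2,Type,Nbr",
           "AVBL,DB1,EJ,2",
           "DB1,MDL08,NMJ,5",
           "DB1,DD1,S,3",
           "DD1,DB1,R,3",     # mirrored duplicate of the S row: skipped
           "DB1,DD1,Sp,1")    # polyadic row for the same pair: summed
  cx <- read_connectome_table(csv, "varshney")
  expect_equal(nrow(cx$electrical), 1)
  expect_equal(nrow(cx$chemical), 2)
  expect_equal(cx$chemical$n_contacts[cx$chemical$post == "DD1"], 4L)
  # no neurotransmitter column in this dialect
  expect_true(all(cx$chemical$neurotransmitter == "UNKNOWN"))
})

test_that("self-connections are dropped with a warning, duplicates merged", {
  csv <- c("Origin,Target,Type,Number of Connections,Neurotransmitter",
           "A,A,Send,2,ACh",
           "A,B,Send,2,Acetylcholine",
           "A,B,Send,3,Acetylcholine",
           "A,B,GapJunction,1,",
           "B,A,GapJunction,1,")
  expect_warning(cx <- read_connectome_table(csv, "wormwiring"), "self-connection")
  expect_equal(nrow(cx$chemical), 1)
  expect_equal(cx$chemical$n_contacts, 5L)
  expect_equal(nrow(cx$electrical), 1)  # mirrored gap rows merge
})

test_that("polarity classification is the GABA rule, case-insensitive", {
  expect_equal(classify_polarity("GABA"), "inhibitory")
  expect_equal(classify_polarity("gaba"), "inhibitory")
  expect_equal(classify_polarity("Acetylcholine"), "excitatory")
  expect_equal(classify_polarity("UNKNOWN"), "excitatory")
  # any vocabulary is partitioned into exactly two classes
  vocab <- c("GABA", "Gaba", "Acetylcholine", "Glutamate", "Serotonin",
             "Dopamine", "UNKNOWN", "Octopamine")
  cls <- classify_polarity(vocab)
  expect_setequal(unique(cls), c("inhibitory", "excitatory"))
  expect_setequal(vocab[cls == "inhibitory"], c("GABA", "Gaba"))
})

test_that("connection weight is contact count times baseline, linear in both", {
  expect_equal(connection_weight(13, 0.01), 0.13)
  expect_equal(connection_weight(1, 0.01), 0.01)
  expect_equal(connection_weight(7, 0), 0)
  for (n in c(1, 2, 5, 13)) {
    for (b in c(0, 0.005, 0.01, 0.2)) {
      expect_equal(connection_weight(n, b), n * b)
      expect_equal(connection_weight(2 * n, b), 2 * connection_weight(n, b))
      expect_equal(connection_weight(n, 2 * b), 2 * connection_weight(n, b))
    }
  }
  expect_error(connection_weight(3, -0.01), ">= 0")
  expect_error(connection_weight(0, 0.01), "positive")
})

test_that("subsetting keeps exactly the named cells and internal edges", {
  cx <- read_connectome_table(ww_fixture_csv(), "wormwiring")
  sub <- subset_connectome(cx, c("DB1", "MDL08"))
  expect_equal(nrow(sub$cells), 2)
  expect_equal(nrow(sub$chemical), 1)
  expect_equal(nrow(sub$electrical), 0)
  one <- subset_connectome(cx, "DB1")
  expect_equal(nrow(one$cells), 1)
  expect_equal(nrow(one$chemical) + nrow(one$electrical), 0)
  expect_error(subset_connectome(cx, c("DB1", "NOPE")), "NOPE")
})

test_that("subsetting agrees with a brute-force edge filter on synthetic wiring", {
  cx <- generate_synthetic_connectome(50, chem_density = 0.1,
                                      gap_density = 0.05, seed = 7)
  set.seed(42)
  for (rep in 1:5) {
    keep <- sample(cx$cells$name, 10)
    sub <- subset_connectome(cx, keep)
    brute_chem <- sum(cx$chemical$pre %in% keep & cx$chemical$post %in% keep)
    brute_elec <- sum(cx$electrical$cell_a %in% keep & cx$electrical$cell_b %in% keep)
    expect_equal(nrow(sub$chemical), brute_chem)
    expect_equal(nrow(sub$electrical), brute_elec)
  }
})

test_that("the synthetic generator is seeded, bounded and binomially sized", {
  a <- generate_synthetic_connectome(20, 4, chem_density = 0.2, seed = 3)
  b <- generate_synthetic_connectome(20, 4, chem_density = 0.2, seed = 3)
  expect_identical(a, b)
  expect_false(identical(
    a, generate_synthetic_connectome(20, 4, chem_density = 0.2, seed = 4)))

  none <- generate_synthetic_connectome(20, chem_density = 0, seed = 1)
  expect_equal(nrow(none$chemical), 0)

  # muscles are never presynaptic; counts are >= 1
  expect_false(any(a$chemical$pre %in% layout_muscles()$name))
  expect_true(all(a$chemical$n_contacts >= 1))

  # realised edge count within 3 sigma of Binomial(50*49, 0.1)
  cx <- generate_synthetic_connectome(50, chem_density = 0.1, seed = 11)
  n_pairs <- 50 * 49
  mu <- n_pairs * 0.1
  sigma <- sqrt(n_pairs * 0.1 * 0.9)
  expect_lt(abs(nrow(cx$chemical) - mu), 3 * sigma)

  expect_error(generate_synthetic_connectome(0), "positive")
  expect_error(generate_synthetic_connectome(10, chem_density = 1.5), "\\[0, 1\\]")
})

test_that("gaba_fraction controls the inhibitory share of synthetic neurons", {
  cx <- generate_synthetic_connectome(200, gaba_fraction = 0.25, seed = 5)
  neurons <- cx$cells[cx$cells$cell_class != "muscle", ]
  frac <- mean(neurons$neurotransmitter == "GABA")
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / 200))
})

test_that("CSV write/read round-trip reproduces the connectome field by field", {
  cx <- read_connectome_table(ww_fixture_csv(), "wormwiring")
  path <- withr::local_tempfile(fileext = ".csv")
  write_connectome_csv(cx, path)
  back <- read_connectome_table(path, "wormwiring")
  expect_equal(back$cells, cx$cells)
  expect_equal(dplyr::arrange(back$chemical, pre, post),
               dplyr::arrange(cx$chemical, pre, post))
  expect_equal(dplyr::arrange(back$electrical, cell_a, cell_b),
               dplyr::arrange(cx$electrical, cell_a, cell_b))

  # edge tables also round-trip for a larger synthetic instance
  syn <- generate_synthetic_connectome(30, 6, chem_density = 0.15,
                                       gap_density = 0.05, seed = 9)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_connectome_csv(syn, path2)
  back2 <- read_connectome_table(path2, "wormwiring")
  expect_equal(dplyr::arrange(back2$chemical, pre, post),
               dplyr::arrange(syn$chemical, pre, post))
  expect_equal(dplyr::arrange(back2$electrical, cell_a, cell_b),
               dplyr::arrange(syn$electrical, cell_a, cell_b))
})

test_that("connectome objects validate their invariants", {
  cells <- tibble::tibble(name = c("A", "A"), cell_class = "interneuron",
                          neurotransmitter = "UNKNOWN", x = 0, y = 0, z = 0)
  expect_error(connectome(cells = cells), "duplicate")
  expect_error(connectome(chemical = tibble::tibble(
    pre = "A", post = "B", n_contacts = 1L, neurotransmitter = "UNKNOWN")),
    "not registered")
})
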