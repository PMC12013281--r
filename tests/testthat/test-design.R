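test_that("generated sequences are uniform permutations", {
  s <- generate_sequence(rng_seed = 1)
  expect_s3_class(s, "sequence_spec")
  expect_identical(sort(as.integer(s)), 1:6)
  expect_identical(as.integer(generate_sequence(rng_seed = 1)),
                   as.integer(s))
  # position-1 occupancy uniform over locations (chi-square goodness of fit)
  set.seed(42)
  firsts <- replicate(10000, generate_sequence()[1])
  p <- chisq.test(table(factor(firsts, levels = 1:6)))$p.value
  expect_gt(p, 1e-4)
})

test_that("successor map is the cyclic successor of the permutation", {
  s <- structure(c(2L, 1L, 6L, 5L, 3L, 4L), class = "sequence_spec")
  succ <- sequence_successor(s)
  expect_identical(succ[2L], 1L) # 2 -> 1
  expect_identical(succ[4L], 2L) # wrap-around: 4 -> 2
  expect_error(sequence_successor(c(1L, 1L, 2L, 3L, 4L, 5L)),
               "permutation")
})

test_that("probabilistic plans have the right size, labels and rates", {
  cfg <- design_config()
  s <- generate_sequence(rng_seed = 3)
  plan <- build_probabilistic_plan(cfg, s, rng_seed = 3)
  expect_equal(nrow(plan), 2016L)
  expect_true(all(plan$stimulus %in% 1:6))
  # no immediate repetitions anywhere, including block boundaries
  expect_false(any(diff(plan$stimulus) == 0))
  # degenerate case: p_regular ~ 1 follows the successor map throughout
  cfg1 <- design_config(p_regular = 1 - 1e-12)
  plan1 <- build_probabilistic_plan(cfg1, s, rng_seed = 4)
  succ <- sequence_successor(s)
  expect_true(all(plan1$stimulus[-1] == succ[plan1$stimulus[-2016]]))
  # pooled regular-transition rate over 50 participants hits p_regular
  set.seed(99)
  hit <- tot <- 0
  for (i in 1:50) {
    sq <- generate_sequence()
    pl <- build_probabilistic_plan(cfg, sq)
    lab <- pl$trial_type[pl$trial_type != "undefined"]
    hit <- hit + sum(lab == "regular")
    tot <- tot + length(lab)
  }
  expect_lt(abs(hit / tot - 0.6), 0.01)
  expect_error(build_probabilistic_plan(
    design_config(material = "mixed_deterministic"), s), "probabilistic")
})

test_that("mixed-deterministic plans alternate block kinds and hit chance rate", {
  cfg <- design_config(material = "mixed_deterministic")
  set.seed(7)
  parities <- character(50)
  hit <- tot <- 0
  for (i in 1:50) {
    sq <- generate_sequence()
    pl <- build_mixed_deterministic_plan(cfg, sq)
    kinds <- tapply(pl$block_kind, pl$block, unique)
    expect_true(all(kinds %in% c("deterministic", "random")))
    # each block pair holds exactly one deterministic and one random block
    for (b in seq(1, 13, 2))
      expect_setequal(kinds[c(b, b + 1)], c("deterministic", "random"))
    parities[i] <- kinds[[1]]
    # deterministic blocks follow the successor map without exception
    succ <- sequence_successor(sq)
    det <- pl$block_kind == "deterministic"
    within_det <- det & c(FALSE, det[-nrow(pl)]) &
      c(FALSE, diff(pl$block) == 0)
    expect_true(all(pl$stimulus[within_det] ==
                      succ[pl$stimulus[which(within_det) - 1L]]))
    rnd <- pl[pl$block_kind == "random" & pl$trial_type != "undefined", ]
    hit <- hit + sum(rnd$trial_type == "regular")
    tot <- tot + nrow(rnd)
    expect_false(any(diff(pl$stimulus) == 0))
  }
  # chance regularity in random blocks: 1/5 = 20% +- 1 point
  expect_lt(abs(hit / tot - 0.2), 0.01)
  # both deterministic parities occur across participants
  expect_setequal(unique(parities), c("deterministic", "random"))
})

test_that("regularity labels follow the sequence-successor rule", {
  s <- structure(c(2L, 1L, 6L, 5L, 3L, 4L), class = "sequence_spec")
  plan <- data.frame(block = c(1L, 1L, 1L, 2L),
                     trial_in_block = c(1L, 2L, 3L, 1L),
                     stimulus = c(2L, 1L, 6L, 3L),
                     block_kind = "probabilistic",
                     deadline_ms = 500)
  lab <- label_regularity(plan, s)
  expect_identical(lab$trial_type, c("undefined", "regular", "regular",
                                     "undefined"))
  # previous = 2, current = 6 is nonregular (6 is not the successor of 2)
  plan$stimulus <- c(4L, 2L, 6L, 3L)
  lab2 <- label_regularity(plan, s)
  expect_identical(lab2$trial_type[2:3], c("regular", "nonregular"))
  plan$stimulus[2] <- 9L
  expect_error(label_regularity(plan, s), "unknown location")
  # p_regular ~ 0 plans still hit 1/5 regular by chance
  cfg0 <- design_config(p_regular = 1e-12,
                        nonregular_excludes_successor = FALSE)
  set.seed(11)
  hit <- tot <- 0
  for (i in 1:20) {
    sq <- generate_sequence()
    pl <- build_probabilistic_plan(cfg0, sq)
    lab <- pl$trial_type[pl$trial_type != "undefined"]
    hit <- hit + sum(lab == "regular"); tot <- tot + length(lab)
  }
  expect_lt(abs(hit / tot - 0.2), 0.015)
})

test_that("instruction phase cycles the sequence for 18 trials", {
  cfg <- design_config(instructions = "revealed")
  s <- generate_sequence(rng_seed = 5)
  ip <- build_instruction_phase(cfg, s)
  expect_equal(nrow(ip), 18L)
  expect_identical(ip$stimulus, rep(as.integer(s), 3))
  expect_true(all(ip$trial_type[-1] == "regular"))
  cfg1 <- design_config(instructions = "revealed", practice_cycles = 1)
  expect_identical(build_instruction_phase(cfg1, s)$stimulus, as.integer(s))
  expect_error(build_instruction_phase(design_config(), s), "revealed")
})

test_that("deadline ramp covers block 1 and the main deadline the rest", {
  cfg <- design_config()
  s <- generate_sequence(rng_seed = 2)
  plan <- build_probabilistic_plan(cfg, s, rng_seed = 2)
  b1 <- plan$deadline_ms[plan$block == 1]
  expect_identical(b1, rep(c(900, 800, 700, 600, 500), c(24, 24, 24, 24, 48)))
  expect_true(all(plan$deadline_ms[plan$block > 1] == 500))
})

test_that("design config validates invariants and round-trips", {
  expect_error(design_config(n_blocks = 13), "even")
  expect_error(design_config(trials_per_block = 100), "divisible")
  expect_error(design_config(p_regular = 1), "p_regular")
  expect_error(design_config(deadline_schedule = data.frame(
    deadline_ms = 900, n_trials = 10)), "sum")
  cfg <- design_config(material = "mixed_deterministic",
                       instructions = "revealed", p_regular = 0.55)
  path <- tempfile(fileext = ".yaml")
  write_design_config(cfg, path)
  expect_equal(read_design_config(path), cfg)
})
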