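test_that("introduce_mutant builds N-1 residents plus one invader", {
  cfg <- two_point_cfg(N = 1000, sd = 0.1)
  set.seed(1)
  st <- introduce_mutant(cfg)
  expect_length(st$alleles, 1000)
  expect_equal(sum(st$alleles == "A"), 999)
  expect_equal(sum(st$alleles == "a"), 1)
  expect_true(all(st$phenotypes[st$alleles == "A"] == 0.8))
  expect_true(st$phenotypes[st$alleles == "a"] %in% support(cfg$invader))
  expect_identical(st$generation, 0L)
})

test_that("forced starts pin the invader phenotype; random start is fair", {
  cfg <- two_point_cfg(N = 10, sd = 0.1)
  sup <- support(cfg$invader)
  set.seed(2)
  expect_identical(introduce_mutant(cfg, "max")$phenotypes[1], max(sup))
  expect_identical(introduce_mutant(cfg, "min")$phenotypes[1], min(sup))
  starts <- vapply(seq_len(1e5), function(i) {
    introduce_mutant(cfg)$phenotypes[1]
  }, numeric(1))
  expect_lt(abs(mean(starts == max(sup)) - 0.5), 0.005)
})

test_that("introduce_mutant guards its preconditions", {
  expect_error(introduce_mutant(two_point_cfg(N = 1)), "N must be >= 2")
  cfg <- sim_config(N = 10, resident = 0.8,
                    invader = phenotype_distribution("uniform", 0.8, 0.05),
                    memory = memory_model("individual", p = 0.5))
  expect_error(introduce_mutant(cfg, "max"), "two_point")
})

test_that("one step conserves N and keeps A individuals at the wild-type phenotype", {
  cfg <- two_point_cfg(N = 200, p = 0.5)
  set.seed(4)
  st <- introduce_mutant(cfg)
  for (i in 1:20) {
    st <- step_generation(st, cfg)
    expect_length(st$alleles, 200)
    expect_true(all(st$phenotypes[st$alleles == "A"] == 0.8))
    if (is_absorbed(st)) break
  }
  expect_equal(st$generation, i)
})

test_that("full memory never resamples: offspring phenotypes come from parents", {
  cfg <- two_point_cfg(N = 100, p = 1)
  set.seed(5)
  st <- introduce_mutant(cfg, "max")
  for (i in 1:10) {
    parents <- unique(st$phenotypes[st$alleles == "a"])
    st2 <- step_generation(st, cfg)
    offspring <- unique(st2$phenotypes[st2$alleles == "a"])
    expect_true(all(offspring %in% parents))
    st <- st2
    if (is_absorbed(st)) break
  }
})

test_that("no memory always resamples: continuous offspring differ from parents", {
  cfg <- sim_config(N = 100, resident = 0.8,
                    invader = phenotype_distribution("uniform", 0.8, 0.05),
                    memory = memory_model("individual", p = 0))
  set.seed(6)
  st <- introduce_mutant(cfg)
  # grow the a-lineage a few generations, then check a full resample
  for (i in 1:30) {
    if (is_absorbed(st)) break
    prev <- st$phenotypes[st$alleles == "a"]
    st <- step_generation(st, cfg)
    cur <- st$phenotypes[st$alleles == "a"]
    # continuous draws almost surely avoid all previous values
    expect_false(any(cur %in% prev))
  }
})

test_that("global memory keeps the a-subpopulation phenotypically uniform", {
  cfg <- two_point_cfg(N = 100, p = 0.6, mode = "global")
  set.seed(7)
  st <- introduce_mutant(cfg)
  for (i in 1:50) {
    if (is_absorbed(st)) break
    st <- step_generation(st, cfg)
    a_ph <- st$phenotypes[st$alleles == "a"]
    if (length(a_ph) > 0) expect_length(unique(a_ph), 1)
  }
})

test_that("a sole parent leaves the allele count unchanged", {
  cfg <- two_point_cfg(N = 2, p = 0.5)
  st <- structure(list(alleles = c("a", "a"), phenotypes = c(0.9, 0.7),
                       generation = 0L), class = "wf_population")
  attr(st, "env0") <- 0L
  expect_error(step_generation(st, cfg), "absorbed")
  # mixed two-individual population keeps N = 2
  st$alleles <- c("a", "A"); st$phenotypes <- c(0.9, 0.8)
  set.seed(8)
  st2 <- step_generation(st, cfg)
  expect_length(st2$alleles, 2)
})

test_that("a neutral step has multinomial expectation equal to the parent count", {
  cfg <- sim_config(N = 1000, resident = 0.8,
                    invader = phenotype_distribution("degenerate", 0.8),
                    memory = memory_model("individual", p = 0.5))
  base <- structure(list(alleles = rep(c("a", "A"), c(300, 700)),
                         phenotypes = rep(0.8, 1000), generation = 0L),
                    class = "wf_population")
  attr(base, "env0") <- 0L
  set.seed(9)
  nrep <- 4e4
  counts <- vapply(seq_len(nrep), function(i) {
    allele_count(step_generation(base, cfg), "a")
  }, integer(1))
  se <- sqrt(1000 * 0.3 * 0.7 / nrep)
  expect_lt(abs(mean(counts) - 300), 3 * se)
})

test_that("identical config and master seed give identical trajectories", {
  cfg <- two_point_cfg(N = 80, p = 0.8)
  run_traj <- function() {
    set.seed(123)
    st <- introduce_mutant(cfg)
    counts <- integer(0)
    while (!is_absorbed(st) && st$generation < 200) {
      st <- step_generation(st, cfg)
      counts <- c(counts, allele_count(st, "a"))
    }
    counts
  }
  expect_identical(run_traj(), run_traj())
})

test_that("run_to_absorption reports outcome and generation consistently", {
  cfg <- two_point_cfg(N = 50, p = 0.9, max_generations = 5000)
  set.seed(10)
  st <- introduce_mutant(cfg)
  res <- run_to_absorption(st, cfg)
  expect_true(res$outcome %in% c("fixation", "loss"))
  expect_equal(res$generation, res$steps)
  # a cutoff of 0 further generations can only discard
  cfg0 <- two_point_cfg(N = 50, p = 0.9, max_generations = 1)
  set.seed(11)
  st <- introduce_mutant(cfg0)
  res0 <- run_to_absorption(st, cfg0)
  expect_true(res0$outcome %in% c("fixation", "loss", "discard"))
})
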