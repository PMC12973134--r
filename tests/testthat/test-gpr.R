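test_that("the GPR grammar parses leaves, precedence and parentheses", {
  leaf <- parse_gpr("g1")
  expect_identical(leaf, list(op = "gene", gene = "g1"))

  # AND binds tighter than OR
  ast <- parse_gpr("g1 and g2 or g3")
  expect_identical(ast$op, "or")
  expect_identical(ast$args[[1]]$op, "and")
  expect_identical(ast$args[[2]]$gene, "g3")

  ast2 <- parse_gpr("g1 and (g2 or g3)")
  expect_identical(ast2$op, "and")
  expect_identical(ast2$args[[2]]$op, "or")

  # operators are case-insensitive; deparse restores precedence
  expect_identical(deparse_gpr(parse_gpr("g1 AND (g2 OR g3)")),
                   "g1 and (g2 or g3)")

  expect_error(parse_gpr("g1 and (g2"), "unbalanced")
  expect_error(parse_gpr(""), "empty")
  expect_error(parse_gpr("g1 g2"), "unexpected")
})

test_that("parse and deparse round-trip random rules", {
  genes <- paste0("gene", 1:8)
  for (seed in 1:20) {
    rule <- random_gpr(genes, depth = 3, seed = seed)
    ast <- parse_gpr(rule)
    expect_identical(parse_gpr(deparse_gpr(ast)), ast)
  }
})

test_that("zero differential expression gives fold change exactly 1 for any rule", {
  genes <- paste0("g", 1:6)
  rules <- vapply(1:15, function(s) random_gpr(genes, 3, seed = 50 + s),
                  character(1))
  model <- gpr_model_from_rules(rules)
  lfc <- setNames(rep(0, 6), genes)
  se <- setNames(rep(0, 6), genes)
  act <- reaction_activity(model, lfc, se, n_draws = 100, seed = 1)
  expect_equal(act$fold_change, rep(1, nrow(act)), tolerance = 1e-12)
  expect_true(all(act$status == "unchanged"))
})

test_that("rule evaluation follows AND = min, OR = sum with baseline 1", {
  model <- gpr_model_from_rules(list("a and b", "a or b", "solo"))
  lfc <- c(a = 1, b = 2, solo = 1)       # linear FC 2 and 4
  se <- c(a = 0, b = 0, solo = 0)
  act <- reaction_activity(model, lfc, se, n_draws = 100, seed = 2)
  expect_equal(act$fold_change[1], 2)    # min(2,4)/min(1,1)
  expect_equal(act$fold_change[2], 3)    # (2+4)/(1+1)
  expect_equal(act$fold_change[3], 2)    # single-gene passthrough
  expect_true(all(act$status[1:3] == "activated"))
})

test_that("raising one gene never lowers any reaction fold change", {
  genes <- paste0("g", 1:5)
  rules <- vapply(1:10, function(s) random_gpr(genes, 3, seed = 80 + s),
                  character(1))
  model <- gpr_model_from_rules(rules)
  se <- setNames(rep(0, 5), genes)
  set.seed(9)
  for (rep in 1:10) {
    lfc <- setNames(rnorm(5, 0, 0.7), genes)
    base <- reaction_activity(model, lfc, se, n_draws = 100, seed = 3)
    bump <- lfc
    g <- sample(genes, 1)
    bump[g] <- bump[g] + runif(1, 0.1, 1)
    after <- reaction_activity(model, bump, se, n_draws = 100, seed = 3)
    expect_true(all(after$fold_change >= base$fold_change - 1e-12))
  }
})

test_that("missing rule genes are treated as neutral", {
  model <- gpr_model_from_rules(list("a and missing_gene"))
  act <- suppressMessages(
    reaction_activity(model, c(a = 2), c(a = 0), n_draws = 100, seed = 4))
  # min(4, 1) / min(1, 1) = 1: the absent complex partner caps the rule
  expect_equal(act$fold_change[1], 1)
})

test_that("activity tables are identical across runs for a fixed seed", {
  model <- read_gpr_model(system.file("extdata", "toy_metabolic_model.json",
                                      package = "uroclust"))
  genes <- unique(unlist(lapply(model$reactions, function(r)
    uroclust:::gpr_genes(r$rule))))
  set.seed(11)
  lfc <- setNames(rnorm(length(genes), 0, 0.6), genes)
  se <- setNames(runif(length(genes), 0.05, 0.3), genes)
  a <- reaction_activity(model, lfc, se, n_draws = 400, seed = 5)
  b <- reaction_activity(model, lfc, se, n_draws = 400, seed = 5)
  expect_identical(a, b)
  expect_true(all(a$lower <= a$fold_change & a$fold_change <= a$upper))
  expect_true(all(a$p >= 1 / 401 & a$p <= 1))
})

test_that("subsystem enrichment flags a fully concentrated significant set", {
  model <- read_gpr_model(system.file("extdata", "toy_metabolic_model.json",
                                      package = "uroclust"))
  target <- model$subsystems[["glycolysis"]]
  activity <- data.frame(reaction = names(model$reactions),
                         status = ifelse(names(model$reactions) %in% target,
                                         "activated", "unchanged"))
  enr <- subsystem_enrichment(activity, model, "activated", n_draws = 2000,
                              seed = 6)
  row <- enr[enr$subsystem == "glycolysis", ]
  expect_equal(row$p, 1 / 2001)
  expect_true(row$or >= 1.44 && row$significant)
  expect_error(subsystem_enrichment(
    data.frame(reaction = "R000", status = "unchanged"), model, "activated"),
    "no significant")
})

test_that("random significant sets rarely produce subsystem flags", {
  model <- read_gpr_model(system.file("extdata", "toy_metabolic_model.json",
                                      package = "uroclust"))
  pool <- names(model$reactions)
  flags <- vapply(1:10, function(sd) {
    set.seed(sd)
    sig <- sample(pool, 8)
    activity <- data.frame(reaction = pool,
                           status = ifelse(pool %in% sig, "activated",
                                           "unchanged"))
    enr <- subsystem_enrichment(activity, model, "activated",
                                n_draws = 2000, seed = sd)
    mean(enr$significant)
  }, numeric(1))
  expect_lte(mean(flags), 0.05)
})
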