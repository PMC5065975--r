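test_that("tilde groups parse into ordered clauses", {
  hs <- parse_hed(fx_examples[["man_ate_fish"]])
  expect_length(hs$elements, 1)
  g <- hs$elements[[1]]
  expect_true(is_hed_group(g))
  expect_length(g$clauses, 3)
  expect_identical(vapply(g$clauses, function(cl) cl[[1]]$text, ""),
                   c("/Item/Object/Person", "/Action/Type/Eat",
                     "/Item/Object/Animal/Fish"))

  g2 <- parse_hed(fx_examples[["car_perturb"]])$elements[[1]]
  expect_length(g2$clauses, 2)
})

test_that("syntax limits are enforced with in-range positions", {
  bad <- list(
    nesting = "((/Event))",
    clauses = "(/A ~ /B ~ /C ~ /D)",
    top_tilde = "/A ~ /B",
    unbalanced = "(/A, /B",
    unbalanced2 = "/A), /B",
    empty = "/A,, /B",
    empty_clause = "(/A ~ )")
  for (nm in names(bad)) {
    err <- tryCatch(parse_hed(bad[[nm]]), error = function(e) e)
    expect_s3_class(err, "hed_syntax_error")
    pos <- as.integer(sub(".*position (\\d+).*", "\\1", conditionMessage(err)))
    expect_gte(pos, 1)
    expect_lte(pos, nchar(bad[[nm]]))
  }
  expect_error(parse_hed("((/Event))"), "one level")
})

test_that("the two-item stimulus example parses as the scanner oracle says", {
  text <- fx_examples[["red_circle"]]
  want <- oracle_scan(text)
  hs <- parse_hed(text)
  expect_length(hs$elements, want$n_top_elements)
  groups <- Filter(is_hed_group, hs$elements)
  expect_length(groups, want$n_groups)
  # 3 ungrouped tags, then the circle group (6 tags, including the
  # participant effect) and the unattended square group (4 tags)
  expect_identical(want$n_top_elements - want$n_groups, 3L)
  sizes <- vapply(groups, function(g) sum(lengths(g$clauses)), 0L)
  expect_identical(sizes, vapply(want$groups, sum, 0L))
  expect_identical(sizes, c(6L, 4L))
})

test_that("serialization canonicalizes spacing and round-trips", {
  expect_identical(serialize_hed(parse_hed("/Event/Label/X,(/A/B ~ /C/D)")),
                   "/Event/Label/X, (/A/B ~ /C/D)")
  set.seed(101)
  for (i in 1:60) {
    text <- random_hed_text()
    hs <- parse_hed(text)
    out <- serialize_hed(hs)
    expect_identical(serialize_hed(parse_hed(out)), out, info = text)
    # whitespace perturbation canonicalizes to the same form
    noisy <- gsub(", ", " ,  ", text, fixed = TRUE)
    expect_identical(serialize_hed(parse_hed(noisy)), out, info = text)
  }
})

test_that("normalize is order-invariant over comma lists and idempotent", {
  expect_identical(normalize_hed("/B, /A"), normalize_hed("/A, /B"))
  set.seed(11)
  for (i in 1:30) {
    tags <- sample(fx_tag_pool, sample(2:5, 1))
    perms <- replicate(4, paste(sample(tags), collapse = ", "))
    norms <- vapply(perms, normalize_hed, "", schema = fx, USE.NAMES = FALSE)
    expect_length(unique(norms), 1)
    expect_identical(normalize_hed(parse_hed(norms[1]), fx), norms[1])
  }
})

test_that("normalize preserves clause order, distinguishing S-P-O readings", {
  ate <- normalize_hed(fx_examples[["man_ate_fish"]], fx)
  reversed <- normalize_hed(
    "(/Item/Object/Animal/Fish ~ /Action/Type/Eat ~ /Item/Object/Person)", fx)
  expect_false(identical(ate, reversed))
})

test_that("normalize folds case to the schema and lower-cases unknowns", {
  expect_identical(normalize_hed("/event/CATEGORY/experimental STIMULUS", fx),
                   "/Event/Category/Experimental stimulus")
  expect_identical(normalize_hed("/Unknown/Branch", fx), "/unknown/branch")
  expect_identical(normalize_hed("/Item/Object/Frobnicator", fx),
                   "/Item/Object/frobnicator")
})

test_that("wildcard substitution fills values", {
  t1 <- substitute_value("/Attribute/Presentation fraction/#", "0.1")
  expect_identical(t1$text, "/Attribute/Presentation fraction/0.1")
  expect_identical(t1$value, "0.1")
  t2 <- substitute_value("/Participant/Effect/Cognitive/Reward/#", "$10")
  expect_identical(t2$text, "/Participant/Effect/Cognitive/Reward/$10")
  expect_error(substitute_value("/Event/Label", "x"), "must end in '#'")
  t3 <- substitute_value("#", "")
  expect_identical(t3$value, "")
})

test_that("values parse against unit classes with defaults and symbols", {
  ucs <- default_unit_classes()
  v <- parse_hed_value("0.1", numeric_required = TRUE)
  expect_true(v$ok); expect_identical(v$number, 0.1)

  v <- parse_hed_value("$10", ucs[["currency"]])
  expect_true(v$ok); expect_identical(v$number, 10); expect_identical(v$unit, "$")

  v <- parse_hed_value("5", ucs[["time"]])
  expect_true(v$ok); expect_identical(v$unit, "s")

  v <- parse_hed_value("5 ms", ucs[["time"]])
  expect_true(v$ok); expect_identical(v$unit, "ms")

  v <- parse_hed_value("5 parsecs", ucs[["time"]])
  expect_false(v$ok); expect_identical(v$reason, "bad_unit")

  v <- parse_hed_value("abc", numeric_required = TRUE)
  expect_false(v$ok); expect_identical(v$reason, "not_numeric")
})
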