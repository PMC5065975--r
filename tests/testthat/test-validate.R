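test_that("label length boundary sits exactly at the warning threshold", {
  lab <- function(k) sprintf("/Event/Label/%s", strrep("a", k))
  for (k in c(1, 10, 19)) {
    expect_false("LABEL_TOO_LONG" %in% validate_tag(lab(k), fx)$code, info = k)
  }
  for (k in c(20, 21, 40)) {
    iss <- validate_tag(lab(k), fx)
    expect_true("LABEL_TOO_LONG" %in% iss$code, info = k)
    expect_identical(iss$severity[iss$code == "LABEL_TOO_LONG"], "warning")
  }
  expect_true("LABEL_TOO_LONG" %in%
                validate_tag("/Event/Label/ThisLabelIsMuchTooLongForHed",
                             fx)$code)
})

test_that("per-tag checks cover values, units, extensions and misses", {
  expect_identical(nrow(validate_tag("/Attribute/Presentation fraction/0.1", fx)),
                   0L)

  iss <- validate_tag("/Attribute/Presentation fraction/abc", fx)
  expect_identical(iss$code, "NOT_NUMERIC")
  expect_identical(iss$severity, "error")

  iss <- validate_tag("/Attribute/Duration/5 parsecs", fx)
  expect_identical(iss$code, "UNIT_INVALID")
  expect_identical(nrow(validate_tag("/Attribute/Duration/5 ms", fx)), 0L)
  expect_identical(nrow(validate_tag("/Attribute/Duration/0.5", fx)), 0L)

  iss <- validate_tag("/Item/Frobnicator", fx)  # /Item is extensionAllowed
  expect_identical(iss$severity, "extension")
  expect_identical(nrow(iss), 1L)

  iss <- validate_tag("/Evnt/Label/x", fx)
  expect_identical(iss$code, "UNKNOWN_TAG")

  # numeric value on a non-value interior node without extensionAllowed
  iss <- validate_tag("/Event/Category/0.5", fx)
  expect_identical(iss$code, "VALUE_FORBIDDEN")

  iss <- validate_tag("/Event/Category", fx)
  expect_identical(iss$code, "CHILD_REQUIRED")

  iss <- validate_tag("/Participant/Effect/Cognitive/Reward/$10", fx)
  expect_identical(nrow(iss), 0L)
})

test_that("string-level checks enforce required, recommended and unique", {
  r <- validate_hed_string(
    paste0(fx_examples[["chair_target"]], ", /Event/Label/chair"), fx)
  expect_identical(nrow(r$errors), 0L)

  r <- validate_hed_string("/Item/Object/Furniture/Chair", fx)
  expect_identical(sort(r$errors$tag[r$errors$code == "REQUIRED_MISSING"]),
                   c("/Event/Category", "/Event/Label"))
  expect_true("RECOMMENDED_MISSING" %in% r$warnings$code)

  two_desc <- paste0("/Event/Category/Incidental, /Event/Label/x, ",
                     "/Event/Description/one, /Event/Description/two")
  r <- validate_hed_string(two_desc, fx)
  expect_true("UNIQUE_VIOLATED" %in% r$errors$code)
})

test_that("issues partition into exactly one report section by severity", {
  mixed <- paste0("/Event/Category/Incidental, /Event/Label/", strrep("z", 25),
                  ", /Event/Description/d, /Evnt/X, /Item/Frobnicator")
  r <- validate_hed_string(mixed, fx)
  all_iss <- rbind(r$errors, r$warnings, r$extensions)
  expect_identical(nrow(all_iss),
                   nrow(r$errors) + nrow(r$warnings) + nrow(r$extensions))
  expect_true(all(r$errors$severity == "error"))
  expect_true(all(r$warnings$severity == "warning"))
  expect_true(all(r$extensions$severity == "extension"))
  expect_identical(r$remap, "/Evnt/X")
})

test_that("event-table validation annotates rows/columns and aggregates remap", {
  tsv <- paste(
    "1.0\t/Event/Category/Incidental, /Event/Label/a, /Event/Description/d1",
    "2.0\t/Evnt/Label/x, /Event/Category/Incidental, /Event/Label/b, /Event/Description/d2",
    "3.0\t/EVNT/Label/x, /Event/Category/Incidental, /Event/Label/c, /Event/Description/d3",
    "shortrow",
    sep = "\n")
  r <- validate_event_table(tsv, 1, 2, FALSE, fx)
  expect_identical(r$errors$row[r$errors$code == "UNKNOWN_TAG"], c(2L, 3L))
  expect_identical(r$errors$column[r$errors$code == "UNKNOWN_TAG"], c(2L, 2L))
  # unique, sorted, case-preserving
  expect_identical(r$remap, c("/EVNT/Label/x", "/Evnt/Label/x"))
  expect_true(any(r$errors$code == "SYNTAX" & r$errors$row == 4L))

  withhdr <- paste("lat\ttags",
                   "1.0\t/Evnt/Q, /Event/Category/Incidental, /Event/Label/a, /Event/Description/d",
                   sep = "\n")
  r2 <- validate_event_table(withhdr, 1, 2, TRUE, fx)
  expect_identical(r2$errors$row[r2$errors$code == "UNKNOWN_TAG"], 2L)
})

test_that("remap corrects whole tags case-insensitively to a fixpoint", {
  tsv <- "1.0\t/Evnt/Label/x, /Event/Category/Incidental, /Event/Description/d"
  rm <- hed_remap("/evnt/label/X", "/Event/Label/x")
  fixed <- apply_remap(tsv, rm, tag_columns = 2)
  r <- validate_event_table(fixed, 1, 2, FALSE, fx)
  expect_length(r$remap, 0)
  expect_identical(nrow(r$errors), 0L)
  # idempotent when no value is a key
  expect_identical(apply_remap(fixed, rm, tag_columns = 2), fixed)
  # empty remap table is the identity
  empty <- hed_remap()
  expect_identical(apply_remap(tsv, empty, tag_columns = 2),
                   apply_remap(tsv, empty, tag_columns = 2))
})

test_that("remap tables load, save and reject duplicates", {
  rm <- load_remap("/Evnt/Label/x\t/Event/Label/x\n/Bad\t/Event")
  expect_identical(rm$keys, c("/Evnt/Label/x", "/Bad"))
  expect_identical(load_remap(save_remap(rm))$values, rm$values)
  expect_error(hed_remap(c("/A", "/a"), c("/B", "/C")), "duplicate")
})

test_that("version translation maps by longest prefix, carrying descendants", {
  mp <- hed_remap(
    c("/Time-locked event/Stimulus", "/A", "/A/B"),
    c("/Event/Category/Experimental stimulus", "/X", "/X/Y"))
  expect_identical(translate_tags("/Time-locked event/Stimulus", mp),
                   "/Event/Category/Experimental stimulus")
  expect_identical(translate_tags("/Time-locked event/Stimulus/Circle", mp),
                   "/Event/Category/Experimental stimulus/Circle")
  expect_identical(translate_tags("/Unrelated/Tag", mp), "/Unrelated/Tag")
  expect_identical(translate_tags("/A/B/C", mp), "/X/Y/C")
})

test_that("validator output reproduces the generator's injection ledger", {
  for (seed in c(11, 23)) {
    g <- gen_events(seed, n_events = 120, error_rate = 0.2, schema = fx)
    r <- validate_event_table(g$text, 1, 3, FALSE, fx)
    got <- rbind(r$errors, r$warnings)[, c("row", "column", "code", "tag")]
    got <- got[order(got$row, got$code), ]
    led <- g$ledger[order(g$ledger$row, g$ledger$code), ]
    rownames(got) <- rownames(led) <- NULL
    expect_identical(got, led, info = paste("seed", seed))
    expect_identical(nrow(r$extensions), 0L)
  }
  clean <- gen_events(5, n_events = 40, error_rate = 0, schema = fx)
  r <- validate_event_table(clean$text, 1, 3, FALSE, fx)
  expect_identical(nrow(r$errors) + nrow(r$warnings), 0L)
})
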