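test_that("the fixture schema has the ten top-level vocabulary classes", {
  roots <- vapply(fx$roots, `[[`, "", "name")
  expect_identical(roots, c("Event", "Item", "Sensory presentation",
                            "Attribute", "Action", "Participant",
                            "Experiment context", "Paradigm", "HED", "Custom"))
  expect_lte(max(vapply(fx$index, `[[`, 0L, "depth")), 7L)
})

test_that("a minimal document parses and structural violations raise", {
  s <- parse_schema_xml("<HED version=\"1\"><node><name>Event</name></node></HED>")
  expect_length(s$roots, 1)
  expect_length(s$unit_classes, 0)

  expect_error(
    parse_schema_xml("<HED><node><name>A</name><node><name>Red</name></node><node><name>red</name></node></node></HED>"),
    "duplicate")
  expect_error(parse_schema_xml("<HED><node><name>A</name>"), "parse error")
  expect_error(
    parse_schema_xml(paste0(
      "<HED><node><name>Duration</name>",
      "<node takesValue=\"true\" unitClass=\"time\"><name>#</name></node>",
      "</node></HED>")),
    "unit class")
})

test_that("hed_locate classifies the worked-example paths", {
  m <- hed_locate(fx, "/Attribute/Presentation fraction/0.1")
  expect_identical(m$kind, "valueMatch")
  expect_identical(m$path, "/Attribute/Presentation fraction")
  expect_identical(m$value, "0.1")

  expect_identical(hed_locate(fx, "/Event")$kind, "exact")
  expect_identical(hed_locate(fx, "/event/CATEGORY")$kind, "exact")

  # /Item/Object/Vehicle is a plain interior node (it has children but no
  # extensionAllowed), so an unknown make is a miss with that ancestor ...
  m <- hed_locate(fx, "/Item/Object/Vehicle/Train")
  expect_identical(m$kind, "miss")
  expect_identical(m$path, "/Item/Object/Vehicle")
  # ... while unknown children under an extensible node extend it, and an
  # unknown branch under another plain interior node is a miss too.
  expect_identical(hed_locate(fx, "/Item/Object/Rock")$kind, "extension")
  m <- hed_locate(fx, "/Event/Category/Nonsense/Deep")
  expect_identical(m$kind, "miss")
  expect_identical(m$path, "/Event/Category")

  expect_error(hed_locate(fx, "  "), "empty")
})

test_that("hed_locate agrees with the brute-force tree-walk oracle", {
  set.seed(42)
  paths <- names(fx$index)
  cases <- c(
    vapply(fx$index, `[[`, "", "path"),                      # exact
    paste0(sample(vapply(fx$index, `[[`, "", "path"), 60), "/xx17"),
    paste0(sample(vapply(fx$index, `[[`, "", "path"), 40), "/a/b"),
    "/Nope", "/Nope/Deeper", "/Attribute/Presentation fraction/0.5")
  for (p in cases) {
    got <- hed_locate(fx, p)
    want <- oracle_locate(fx, p)
    expect_identical(got$kind, want$kind, info = p)
    expect_identical(got$matched_depth, want$depth, info = p)
  }
})

test_that("locate oracle agreement holds on generated schemas", {
  for (seed in c(3, 9)) {
    s <- gen_schema(seed, depth = 4, branching = 3)
    paths <- vapply(s$index, `[[`, "", "path")
    set.seed(seed)
    cases <- c(paths,
               paste0(sample(paths, min(30, length(paths)), replace = TRUE),
                      "/Extra"),
               "/Absent/Node")
    for (p in cases) {
      expect_identical(hed_locate(s, p)$kind, oracle_locate(s, p)$kind,
                       info = paste(seed, p))
    }
  }
})

test_that("schema_search finds fragments and is monotone in the fragment", {
  expect_true("/Item/2D shape/Ellipse/Circle" %in% schema_search(fx, "circ"))
  expect_true("/Event/Category" %in% schema_search(fx, "Category"))
  expect_length(schema_search(fx, "zzz-not-present"), 0)

  for (frag in c("c", "ca", "cat", "s", "sc", "scr")) {
    longer <- paste0(frag, "e")
    expect_true(all(schema_search(fx, longer) %in% schema_search(fx, frag)),
                info = frag)
  }
})

test_that("nodes_at_level partitions the schema by depth", {
  expect_setequal(nodes_at_level(fx, 1),
                  paste0("/", vapply(fx$roots, `[[`, "", "name")))
  expect_length(nodes_at_level(fx, 20), 0)
  expect_error(nodes_at_level(fx, 0), "positive")

  total <- sum(vapply(1:10, function(l) length(nodes_at_level(fx, l)), 0L))
  expect_identical(total, length(fx$index))
})

test_that("check_schema reports structural faults and passes the fixture", {
  expect_identical(nrow(check_schema(fx)), 0L)

  dup <- hed_schema(list(hed_node("A", hed_node("Red"), hed_node("red"))),
                    check = FALSE)
  expect_true("DUPLICATE_SIBLING" %in% check_schema(dup)$code)

  bad_uc <- hed_schema(
    list(hed_node("A")),
    list(structure(list(name = "time", units = c("s", "ms"),
                        default = "parsec"), class = "hed_unit_class")),
    check = FALSE)
  expect_true("DEFAULT_UNIT_INVALID" %in% check_schema(bad_uc)$code)

  no_val <- hed_schema(
    list(hed_node("A", hed_node("B", attrs = list(isNumeric = TRUE)))),
    check = FALSE)
  expect_true("NUMERIC_NOT_VALUE" %in% check_schema(no_val)$code)
})

test_that("unit-class invariants are enforced at construction", {
  expect_error(hed_unit_class("time", c("s", "ms"), "h"), "default unit")
  expect_error(hed_unit_class("time", character(), "s"), "no allowed units")
  uc <- default_unit_classes()
  expect_true(all(vapply(uc, function(u) u$default %in% u$units, NA)))
})
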