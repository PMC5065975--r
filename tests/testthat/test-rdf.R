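base <- "http://hedtags.org/schema/v2/"
rdf_type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
rdfs <- "http://www.w3.org/2000/01/rdf-schema#"

test_that("annotation URIs are normalization-stable and decodable", {
  expect_identical(hed_string_uri("/B, /A", base), hed_string_uri("/A, /B", base))
  u1 <- hed_string_uri("(/S ~ /P ~ /O)", base)
  u2 <- hed_string_uri("(/O ~ /P ~ /S)", base)
  expect_false(identical(u1, u2))
  norm <- normalize_hed("/Event/Label/My Event, /Attribute/Visual/Color/Red", fx)
  uri <- hed_string_uri(norm, base, fx)
  expect_identical(utils::URLdecode(sub(base, "", uri, fixed = TRUE)), norm)
})

test_that("label and description values become rdfs:label / rdfs:comment", {
  tr <- instance_triples(
    "http://x/E1",
    paste0("/Event/Category/Experimental stimulus, ",
           "/Event/Label/RedFixationCircle, /Event/Description/A red circle"),
    fx, base)
  lab <- tr[tr$predicate == paste0(rdfs, "label"), ]
  expect_identical(lab$object, "RedFixationCircle")
  expect_true(lab$literal)
  com <- tr[tr$predicate == paste0(rdfs, "comment"), ]
  expect_identical(com$object, "A red circle")
  # type statement links the event to its normalized-annotation URI
  ty <- tr[tr$predicate == rdf_type, ]
  expect_identical(ty$subject, "http://x/E1")
  expect_true(startsWith(ty$object, paste0(base, "HEDString/")))
})

test_that("every worked example yields type triples; labels where present", {
  for (nm in names(fx_examples)) {
    tr <- instance_triples(paste0("http://x/", nm), fx_examples[[nm]], fx, base)
    expect_identical(sum(tr$predicate == rdf_type), 1L, info = nm)
  }
  tr <- instance_triples("http://x/rc", fx_examples[["red_circle"]], fx, base)
  expect_true(any(tr$predicate == paste0(rdfs, "label") &
                    tr$object == "RedFixationCircle"))
  expect_true(any(tr$predicate == paste0(rdfs, "comment")))
})

test_that("the subject-predicate-object group emits the rule-table triples", {
  tr <- instance_triples("http://x/E", fx_examples[["man_ate_fish"]], fx, base)
  turi <- function(p) paste0(base, "HEDTag/", utils::URLencode(p, reserved = TRUE))
  # Action isPerformedBy Item, for both Items in the group, and nothing else
  rel <- tr[grepl(paste0(base, "(isDescribedBy|isPerformedBy|presents|",
                         "describes|performs|isPresentedBy)"), tr$predicate), ]
  want <- data.frame(
    subject = rep(turi("/Action/Type/Eat"), 2),
    predicate = rep(paste0(base, "isPerformedBy"), 2),
    object = c(turi("/Item/Object/Person"), turi("/Item/Object/Animal/Fish")),
    stringsAsFactors = FALSE)
  got <- rel[order(rel$object), c("subject", "predicate", "object")]
  want <- want[order(want$object), ]
  rownames(got) <- rownames(want) <- NULL
  expect_identical(got, want)

  # one statement whose subject/predicate/object are the clause URIs
  spo <- tr[startsWith(tr$predicate, paste0(base, "HEDClause/")), ]
  expect_identical(nrow(spo), 1L)
  expect_match(spo$subject, "Person")
  expect_match(spo$predicate, "Eat")
  expect_match(spo$object, "Fish")

  # a two-clause group carries no S-P-O statement
  tr2 <- instance_triples("http://x/E2", fx_examples[["car_perturb"]], fx, base)
  expect_false(any(startsWith(tr2$predicate, paste0(base, "HEDClause/"))))
  expect_true(any(tr2$predicate == paste0(base, "isDescribedBy")))
})

test_that("attribute relations stay within a group; inverses only on request", {
  tr <- instance_triples("http://x/E", fx_examples[["red_circle"]], fx, base)
  desc_by <- tr[tr$predicate == paste0(base, "isDescribedBy"), ]
  circle <- paste0(base, "HEDTag/",
                   utils::URLencode("/Item/2D shape/Ellipse/Circle",
                                    reserved = TRUE))
  red <- paste0(base, "HEDTag/",
                utils::URLencode("/Attribute/Visual/Color/Red",
                                 reserved = TRUE))
  blue <- paste0(base, "HEDTag/",
                 utils::URLencode("/Attribute/Visual/Color/Blue",
                                  reserved = TRUE))
  expect_true(any(desc_by$subject == circle & desc_by$object == red))
  # Blue describes only the square's group, never the circle across groups
  expect_false(any(desc_by$subject == circle & desc_by$object == blue))
  # default emission has no inverse rows
  expect_false(any(tr$predicate == paste0(base, "describes")))

  tri <- instance_triples("http://x/E", fx_examples[["red_circle"]], fx, base,
                          inverse = TRUE)
  inv <- tri[tri$predicate == paste0(base, "describes"), ]
  expect_true(any(inv$subject == red & inv$object == circle))
  # inverse closure: each isDescribedBy has its describes mirror
  fwd <- tri[tri$predicate == paste0(base, "isDescribedBy"), ]
  for (i in seq_len(nrow(fwd))) {
    expect_true(any(inv$subject == fwd$object[i] & inv$object == fwd$subject[i]))
  }
})

test_that("property-typed nodes export with isPropertyOf", {
  tr <- instance_triples(
    "http://x/E",
    "/Event/Category/Incidental, /Event/Label/x, /Participant/ID/3", fx, base)
  prop <- tr[tr$predicate == paste0(base, "isPropertyOf"), ]
  expect_identical(nrow(prop), 1L)
  expect_match(prop$subject, "Participant%2FID%2F3")
  # subclass tags use hasTag membership instead
  expect_true(any(tr$predicate == paste0(base, "hasTag")))
})

test_that("N-Triples and Turtle serializations are well-formed", {
  tr <- instance_triples("http://x/E", fx_examples[["chair_target"]], fx, base)
  nt <- write_ntriples(tr)
  lines <- strsplit(nt, "\n")[[1]]
  expect_length(lines, nrow(tr))
  expect_true(all(grepl("^<[^>]+> <[^>]+> (<[^>]+>|\"[^\"]*\") \\.$", lines)))
  ttl <- write_turtle(tr)
  expect_match(ttl, "@prefix rdfs?:", all = FALSE)

  tmp <- withr::local_tempfile(fileext = ".nt")
  write_ntriples(tr, tmp)
  expect_identical(paste0(paste(readLines(tmp), collapse = "\n"), "\n"), nt)
})

test_that("triple emission is deterministic given the same input", {
  a <- event_table_triples(
    read_events_tsv("1\t/Event/Category/Incidental, /Event/Label/x"), fx)
  b <- event_table_triples(
    read_events_tsv("1\t/Event/Category/Incidental, /Event/Label/x"), fx)
  expect_identical(a, b)
})
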