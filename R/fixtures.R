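# Bundled fixture vocabulary: a curated ~100-node subset of the community
# HED 2.0 hierarchy, sufficient to resolve every worked-example annotation
# shipped with the package.  Full-vocabulary files can be ingested with the
# schema readers; no copy is bundled.

#' The bundled fixture schema
#'
#' A compact vocabulary whose ten roots are the top-level classes of the
#' HED 2.0 hierarchy (Event, Item, Sensory presentation, Attribute, Action,
#' Participant, Experiment context, Paradigm, HED, Custom) and which
#' resolves every path used by [example_annotations()].  `/Event/Category`
#' and `/Event/Label` are required (with children), `/Event/Description` is
#' recommended and unique; `/Attribute/Presentation fraction` takes a
#' numeric value, `/Participant/Effect/Cognitive/Reward` a currency value,
#' and `/Participant/ID` (a property node, default 1) a numeric value.
#'
#' @return A `hed_schema` that passes [check_schema()] cleanly.
#' @export
fixture_schema <- function() {
  n <- hed_node
  hash <- function(...) n("#", attrs = c(list(takesValue = TRUE), list(...)))

  event <- n("Event",
    n("Category",
      n("Initial context"), n("Participant response"), n("Technical error"),
      n("Participant failure"), n("Environmental"), n("Experimental stimulus"),
      n("Experimental procedure"), n("Incidental"), n("Miscellaneous"),
      n("Experimental control"),
      attrs = list(required = TRUE, childRequired = TRUE),
      description = "The general category of the event."),
    n("Label", hash(),
      attrs = list(required = TRUE, childRequired = TRUE),
      description = "A short study-specific identifier for events of this type."),
    n("Description", hash(),
      attrs = list(recommended = TRUE, unique = TRUE, childRequired = TRUE),
      description = "A human-readable description of what the event represents."),
    description = "Something that happens at a moment or over an interval.")

  item <- n("Item",
    n("ID", hash(isNumeric = TRUE),
      attrs = list(predicateType = "property")),
    n("Group ID", hash(isNumeric = TRUE),
      attrs = list(predicateType = "property")),
    n("2D shape",
      n("Ellipse", n("Circle")),
      n("Rectangle", n("Square")),
      n("Star")),
    n("Object",
      n("Person"),
      n("Animal", n("Fish")),
      n("Vehicle", n("Car")),
      n("Furniture", n("Chair")),
      attrs = list(extensionAllowed = TRUE)),
    attrs = list(extensionAllowed = TRUE),
    description = "A thing that can be presented or take part in an event.")

  sensory <- n("Sensory presentation",
    n("Visual",
      n("Rendering type",
        n("Screen", n("2D"), n("3D"))),
      attrs = list(extensionAllowed = TRUE)),
    n("Auditory"),
    description = "How an item reaches the participant's senses.")

  attribute <- n("Attribute",
    n("Visual",
      n("Color", n("Red"), n("Blue"), n("Green"))),
    n("Fixation point"),
    n("Location",
      n("Screen", n("Center"), n("Left"), n("Right"), n("Top"), n("Bottom"))),
    n("Presentation fraction", hash(isNumeric = TRUE),
      description = "Fraction of presented stimuli belonging to this class."),
    n("Vehicle Control", n("Perturb"), n("Brake"), n("Steer")),
    n("Onset"), n("Offset"),
    n("Duration", hash(isNumeric = TRUE, unitClass = "time")),
    n("Temporal rate", hash(isNumeric = TRUE, unitClass = "frequency")),
    n("Size",
      n("Length", hash(isNumeric = TRUE, unitClass = "physicalLength"))),
    n("Angle", hash(isNumeric = TRUE, unitClass = "angle")),
    attrs = list(extensionAllowed = TRUE),
    description = "Descriptive modifiers, orthogonal to the items they describe.")

  action <- n("Action",
    n("Type",
      n("Eat"), n("Walk"), n("Press"), n("Look"),
      attrs = list(extensionAllowed = TRUE)),
    description = "An action performed by a participant or item.")

  participant <- n("Participant",
    n("ID", hash(isNumeric = TRUE),
      attrs = list(predicateType = "property", default = "1")),
    n("Role", n("Experimenter"), n("Subject")),
    n("Effect",
      n("Visual"), n("Auditory"),
      n("Cognitive",
        n("Target"), n("Oddball"), n("Threat"),
        n("Reward", hash(unitClass = "currency")))),
    n("State", n("Attention"), n("Fatigue"),
      attrs = list(extensionAllowed = TRUE)),
    description = "The participant, their role, state and the event's effect.")

  context <- n("Experiment context", n("Indoors"), n("Outdoors"),
               attrs = list(extensionAllowed = TRUE))
  paradigm <- n("Paradigm", n("Visual oddball"), n("N-back"), n("Driving"),
                attrs = list(extensionAllowed = TRUE))

  hed_schema(
    list(event, item, sensory, attribute, action, participant, context,
         paradigm,
         n("HED", attrs = list(extensionAllowed = TRUE)),
         n("Custom", attrs = list(extensionAllowed = TRUE))),
    default_unit_classes(), version = "2.0")
}

#' Worked-example annotation strings
#'
#' The package's stock of example annotations: a red fixation circle
#' presented together with an unattended blue square, a chair target in a
#' visual oddball task, the oddball tag pair with its presentation
#' fraction, and the tilde-clause groups "Man ate Fish" and "Car is
#' perturbed".  All parse cleanly and, after a label is added where an
#' example omits one, validate against [fixture_schema()] without errors.
#'
#' @return Named character vector of annotation strings.
#' @export
example_annotations <- function() {
  c(
    red_circle = paste0(
      "/Event/Category/Experimental stimulus, ",
      "/Event/Label/RedFixationCircle, ",
      "/Event/Description/Displayed to user a red circle for fixation in ",
      "center of the screen and a blue square on the left. ",
      "User sees the red circle, ",
      "(/Item/2D shape/Ellipse/Circle, /Attribute/Visual/Color/Red, ",
      "/Attribute/Fixation point, /Attribute/Location/Screen/Center, ",
      "/Sensory presentation/Visual/Rendering type/Screen/2D, ",
      "/Participant/Effect/Visual), ",
      "(/Item/2D shape/Rectangle/Square, /Attribute/Visual/Color/Blue, ",
      "/Attribute/Location/Screen/Left, ",
      "/Sensory presentation/Visual/Rendering type/Screen/2D)"),
    chair_target = paste0(
      "/Event/Category/Experimental stimulus, ",
      "/Event/Description/A picture chair is displayed on the screen, ",
      "/Sensory presentation/Visual, /Participant/Effect/Visual, ",
      "/Participant/Effect/Cognitive/Target, /Item/Object/Furniture/Chair"),
    oddball_pair = paste0(
      "/Participant/Effect/Cognitive/Oddball, ",
      "/Attribute/Presentation fraction/0.1"),
    man_ate_fish =
      "(/Item/Object/Person ~ /Action/Type/Eat ~ /Item/Object/Animal/Fish)",
    car_perturb =
      "(/Item/Object/Vehicle/Car ~ /Attribute/Vehicle Control/Perturb)"
  )
}

#' Write the bundled fixture artifacts to a directory
#'
#' Emits the fixture schema in both dialects (`hed-fixture.xml`,
#' `hed-fixture.wiki`), the worked-example strings
#' (`example-annotations.tsv`: name, annotation), and a small seeded demo
#' event table with its tag map (`demo_events.tsv`, `demo_map.tsv`).
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Seed for the demo event table.
#' @return Invisibly, the paths written.
#' @export
emit_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  schema <- fixture_schema()
  paths <- c(
    xml = file.path(out_dir, "hed-fixture.xml"),
    wiki = file.path(out_dir, "hed-fixture.wiki"),
    examples = file.path(out_dir, "example-annotations.tsv"),
    events = file.path(out_dir, "demo_events.tsv"),
    map = file.path(out_dir, "demo_map.tsv"))
  writeLines(sub("\n$", "", serialize_schema_xml(schema)), paths[["xml"]])
  writeLines(sub("\n$", "", serialize_schema_wiki(schema)), paths[["wiki"]])
  ex <- example_annotations()
  writeLines(paste(names(ex), ex, sep = "\t"), paths[["examples"]])
  gen <- gen_events(seed, n_events = 20, error_rate = 0, schema = schema)
  writeLines(sub("\n$", "", gen$text), paths[["events"]])
  ex <- example_annotations()
  map_lines <- c(
    paste0("square\t", ex[["red_circle"]]),
    paste0("rt\t/Event/Category/Participant response, /Event/Label/rt, ",
           "/Event/Description/Participant presses the response button, ",
           "/Action/Type/Press"))
  writeLines(map_lines, paths[["map"]])
  invisible(paths)
}
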