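# Prompt composition. Prompts are assembled from configurable plain-text
# blocks in a fixed order; the wording is data (shipped defaults under
# inst/extdata/prompts/), the composition is the contract. Four variants
# are supported — Minimal, Minimal+DK, Minimal+Guide, Minimal+DK+Guide —
# where DK adds domain-knowledge explanations per extraction item and
# Guide adds a step-by-step extraction procedure. Single-shot extraction
# prepends filter statements with the target-experiment criteria to the
# full Minimal+DK+Guide prompt.

PROMPT_VARIANTS <- c("minimal", "minimal_dk", "minimal_guide",
                     "minimal_dk_guide")

#' Prompt block set
#'
#' @param minimal Required: target conditions + brief instructions.
#' @param dk Optional domain-knowledge block.
#' @param guide Optional step-by-step extraction guide.
#' @param filter Optional single-shot filter criteria block.
#' @param output_schema Structured-output instruction; defaults to a
#'   JSON-array schema naming the canonical fields.
#' @return A `prompt_blocks` object.
#' @export
prompt_blocks <- function(minimal, dk = NULL, guide = NULL, filter = NULL,
                          output_schema = default_output_schema()) {
  if (missing(minimal) || !nzchar(minimal)) {
    llps_config_error("the 'minimal' block is always required")
  }
  structure(list(minimal = minimal, dk = dk, guide = guide, filter = filter,
                 output_schema = output_schema),
            class = "prompt_blocks")
}

#' Default prompt blocks shipped with the package
#' @return A [prompt_blocks] object read from the installed text files.
#' @export
default_prompt_blocks <- function() {
  read_block <- function(name) {
    path <- system.file("extdata", "prompts", paste0(name, ".txt"),
                        package = "llpsie")
    paste(readLines(path, encoding = "UTF-8"), collapse = "\n")
  }
  prompt_blocks(minimal = read_block("minimal"),
                dk = read_block("dk"),
                guide = read_block("guide"),
                filter = read_block("filter"),
                output_schema = read_block("output_schema"))
}

default_output_schema <- function() {
  paste(
    "Return the result as a JSON array, one object per experiment, with",
    "exactly these keys: protein_name, protein_conc, rna_conc, ph,",
    "temperature, phase_status, sequence_region, modification_state.",
    "Use null for any condition not determinable. Output the JSON array",
    "only, no commentary.", sep = "\n")
}

#' Figure-targeting directive
#'
#' Names the figure (and optionally subfigure panel and its position on
#' the page, e.g. "left" when several plots share one panel) that a
#' figure-by-figure call must restrict itself to.
#'
#' @param figure_id Figure identifier, e.g. `"Fig 2E"`.
#' @param subfigure_id Optional panel identifier.
#' @param position One of `"none"`, `"left"`, `"right"`, `"top"`,
#'   `"bottom"`; only meaningful with a subfigure.
#' @return A `figure_directive` object.
#' @export
figure_directive <- function(figure_id, subfigure_id = NULL,
                             position = c("none", "left", "right", "top",
                                          "bottom")) {
  position <- match.arg(position)
  if (position != "none" && is.null(subfigure_id)) {
    llps_config_error(
      "a position qualifier requires a subfigure identifier")
  }
  structure(list(figure_id = figure_id, subfigure_id = subfigure_id,
                 position = position),
            class = "figure_directive")
}

directive_text <- function(directive) {
  txt <- sprintf(
    "Extract only the experiments presented in figure %s",
    directive$figure_id)
  if (!is.null(directive$subfigure_id)) {
    txt <- sprintf("%s, panel %s", txt, directive$subfigure_id)
  }
  if (directive$position != "none") {
    txt <- sprintf("%s (the %s plot)", txt, directive$position)
  }
  paste0(txt, ".")
}

#' Compose an extraction prompt
#'
#' Deterministic concatenation, in fixed order, of: minimal, DK (if the
#' variant requests it), Guide (likewise), the output schema, and the
#' figure-targeting directive. Identical inputs yield byte-identical
#' output.
#'
#' @param blocks A [prompt_blocks] object.
#' @param variant One of `"minimal"`, `"minimal_dk"`, `"minimal_guide"`,
#'   `"minimal_dk_guide"`.
#' @param directive Optional [figure_directive].
#' @return The prompt string.
#' @export
compose_prompt <- function(blocks, variant = PROMPT_VARIANTS,
                           directive = NULL) {
  variant <- match.arg(variant)
  parts <- list(blocks$minimal)
  if (variant %in% c("minimal_dk", "minimal_dk_guide")) {
    if (is.null(blocks$dk)) {
      llps_config_error(sprintf(
        "variant '%s' requires the 'dk' block, which is absent", variant))
    }
    parts <- c(parts, blocks$dk)
  }
  if (variant %in% c("minimal_guide", "minimal_dk_guide")) {
    if (is.null(blocks$guide)) {
      llps_config_error(sprintf(
        "variant '%s' requires the 'guide' block, which is absent", variant))
    }
    parts <- c(parts, blocks$guide)
  }
  parts <- c(parts, blocks$output_schema)
  if (!is.null(directive)) parts <- c(parts, directive_text(directive))
  paste(unlist(parts), collapse = "\n\n")
}

#' Compose the single-shot (whole-paper) prompt
#'
#' Filter criteria first, then the full Minimal+DK+Guide prompt and the
#' output schema. All four blocks are required.
#'
#' @param blocks A [prompt_blocks] object with a `filter` block.
#' @return The prompt string.
#' @export
compose_single_shot_prompt <- function(blocks) {
  if (is.null(blocks$filter)) {
    llps_config_error("single-shot composition requires the 'filter' block")
  }
  for (b in c("dk", "guide")) {
    if (is.null(blocks[[b]])) {
      llps_config_error(sprintf(
        "single-shot composition requires the '%s' block, which is absent", b))
    }
  }
  paste(blocks$filter, blocks$minimal, blocks$dk, blocks$guide,
        blocks$output_schema, sep = "\n\n")
}
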