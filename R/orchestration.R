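# Driving extraction runs. A backend is any R function taking a
# `backend_call` and returning a `backend_response`; live API adapters
# plug in through that contract, while the shipped mock backends make
# the whole pipeline testable offline. Four input patterns are
# supported: figure only, figure + caption/methods text, figure + full
# text, and whole PDF. Figure-by-figure runs issue exactly one call per
# figure directive; single-shot runs issue exactly one call per paper.

INPUT_PATTERNS <- c("figure", "figure_cm", "figure_fulltext", "pdf")

#' Paper bundle
#'
#' The per-paper input material: subfigure images with their directives,
#' caption+methods text, full text, and/or the PDF.
#'
#' @param paper_id Paper identifier.
#' @param figures List of `list(directive = figure_directive, image =
#'   path)` entries.
#' @param caption_method_text,full_text Optional text components.
#' @param pdf Optional PDF path.
#' @return A `paper_bundle` object.
#' @export
paper_bundle <- function(paper_id, figures = list(),
                         caption_method_text = NULL, full_text = NULL,
                         pdf = NULL) {
  for (fg in figures) {
    if (!inherits(fg$directive, "figure_directive") || is.null(fg$image)) {
      llps_config_error(
        "each figure entry needs a figure_directive and an image path")
    }
  }
  structure(list(paper_id = paper_id, figures = figures,
                 caption_method_text = caption_method_text,
                 full_text = full_text, pdf = pdf),
            class = "paper_bundle")
}

#' Assemble the input payload for one call
#'
#' Selects exactly the bundle components the pattern requires — nothing
#' else leaks into the payload — and fails with a configuration error
#' before any backend is invoked if a component is missing.
#'
#' @param bundle A [paper_bundle].
#' @param pattern One of `"figure"`, `"figure_cm"`, `"figure_fulltext"`,
#'   `"pdf"`.
#' @param directive The [figure_directive] being targeted; required for
#'   the figure-scoped patterns.
#' @return List with `attachments` (list of `list(kind, path)`) and
#'   `inline_text` (or `NULL`).
#' @export
assemble_input <- function(bundle, pattern = INPUT_PATTERNS,
                           directive = NULL) {
  pattern <- match.arg(pattern)
  if (pattern == "pdf") {
    if (is.null(bundle$pdf)) {
      llps_config_error(sprintf(
        "pattern 'pdf' requires a PDF in the bundle for paper %s",
        bundle$paper_id))
    }
    return(list(attachments = list(list(kind = "pdf", path = bundle$pdf)),
                inline_text = NULL))
  }
  if (is.null(directive)) {
    llps_config_error(sprintf(
      "pattern '%s' requires a figure directive", pattern))
  }
  entry <- NULL
  for (fg in bundle$figures) {
    if (identical(fg$directive$figure_id, directive$figure_id) &&
        identical(fg$directive$subfigure_id, directive$subfigure_id)) {
      entry <- fg
      break
    }
  }
  if (is.null(entry)) {
    llps_config_error(sprintf(
      "bundle for paper %s has no image for figure %s",
      bundle$paper_id, directive$figure_id))
  }
  inline <- switch(pattern,
    figure = NULL,
    figure_cm = {
      if (is.null(bundle$caption_method_text)) {
        llps_config_error(
          "pattern 'figure_cm' requires caption+methods text in the bundle")
      }
      bundle$caption_method_text
    },
    figure_fulltext = {
      if (is.null(bundle$full_text)) {
        llps_config_error(
          "pattern 'figure_fulltext' requires the full text in the bundle")
      }
      bundle$full_text
    })
  list(attachments = list(list(kind = "image", path = entry$image)),
       inline_text = inline)
}

#' Backend call / response
#'
#' `backend_call` is the unit of work handed to a backend: the rendered
#' prompt, attachments, model name, sampling temperature (default 0.0)
#' and optional seed; `tag` carries the processing-unit key (figure id
#' or `"paper"`) for scripted mocks. `backend_response` captures the raw
#' model text verbatim plus token counts when the backend reports them.
#'
#' @param prompt Prompt string.
#' @param attachments List of `list(kind, path)`.
#' @param model_name Model identifier.
#' @param temperature Sampling temperature in \[0, 2\]; default 0.
#' @param seed Optional integer seed.
#' @param tag Processing-unit key.
#' @return A `backend_call` object.
#' @export
backend_call <- function(prompt, attachments = list(), model_name = "mock",
                         temperature = 0, seed = NULL, tag = NULL) {
  if (temperature < 0 || temperature > 2) {
    llps_config_error("sampling temperature must be in [0, 2]")
  }
  structure(list(prompt = prompt, attachments = attachments,
                 model_name = model_name, temperature = temperature,
                 seed = seed, tag = tag),
            class = "backend_call")
}

#' @rdname backend_call
#' @param text Raw model output.
#' @param token_counts Optional `list(input =, output =)`.
#' @export
backend_response <- function(text, token_counts = NULL) {
  structure(list(text = text, token_counts = token_counts),
            class = "backend_response")
}

#' Scripted mock backend
#'
#' Returns a backend function that replays canned responses keyed by the
#' call's `tag` (figure id, or `"paper"` for single-shot). Calls are
#' counted; read the count with [backend_call_count()]. Unknown tags get
#' an empty-prose response.
#'
#' @param responses Named list/character of response texts.
#' @return A backend function.
#' @export
mock_backend <- function(responses = list()) {
  env <- new.env(parent = emptyenv())
  env$n_calls <- 0L
  env$calls <- list()
  f <- function(call) {
    env$n_calls <- env$n_calls + 1L
    env$calls[[env$n_calls]] <- call
    txt <- responses[[call$tag %||% "paper"]] %||% ""
    backend_response(txt, token_counts = list(
      input = nchar(call$prompt), output = nchar(txt)))
  }
  attr(f, "env") <- env
  class(f) <- c("llps_backend", "function")
  f
}

#' Number of calls a mock backend has received
#' @param backend A backend from [mock_backend()] or
#'   [scenario_backend()].
#' @return Integer call count.
#' @export
backend_call_count <- function(backend) {
  attr(backend, "env")$n_calls
}

retry_call <- function(backend, call, retries = 3) {
  for (attempt in seq_len(retries + 1)) {
    res <- tryCatch(backend(call), llps_transport_error = function(e) e)
    if (!inherits(res, "condition")) return(res)
    if (attempt > retries) stop(res)
  }
}

#' Run figure-by-figure extraction
#'
#' One backend call per figure directive, in bundle order. Each response
#' is parsed, normalized and scoped to its figure. Failures are isolated
#' per figure: transport errors are retried (exponential strategy is the
#' backend adapter's concern; model-content errors are never retried),
#' and a figure whose response cannot be parsed yields an empty record
#' set annotated with the diagnostics.
#'
#' @param bundle A [paper_bundle].
#' @param pattern Input pattern (see [assemble_input()]).
#' @param blocks [prompt_blocks].
#' @param variant Prompt variant (see [compose_prompt()]).
#' @param backend Backend function.
#' @param rules [normalization_rules] for post-processing.
#' @param model_name,temperature,seed Forwarded into each call.
#' @param retries Transport-error retries per figure (default 3).
#' @return List of per-figure [record_set]s (bundle order), with a run
#'   manifest in attribute `"manifest"`.
#' @export
run_figure_by_figure <- function(bundle, pattern, blocks,
                                 variant = "minimal_dk_guide", backend,
                                 rules = default_rules(),
                                 model_name = "mock", temperature = 0,
                                 seed = NULL, retries = 3) {
  out <- list()
  tokens <- c(input = 0L, output = 0L)
  n_calls <- 0L
  for (fg in bundle$figures) {
    directive <- fg$directive
    prompt <- compose_prompt(blocks, variant, directive)
    payload <- assemble_input(bundle, pattern, directive)
    if (!is.null(payload$inline_text)) {
      prompt <- paste(prompt, payload$inline_text, sep = "\n\n")
    }
    call <- backend_call(prompt, payload$attachments, model_name,
                         temperature, seed, tag = directive$figure_id)
    rs <- tryCatch({
      res <- retry_call(backend, call, retries)
      n_calls <- n_calls + 1L
      if (!is.null(res$token_counts)) {
        tokens <- tokens + c(input = res$token_counts$input %||% 0L,
                             output = res$token_counts$output %||% 0L)
      }
      parsed <- parse_model_output(res$text)
      rs <- normalize_records(parsed$records, rules,
                              paper_id = bundle$paper_id,
                              figure_id = directive$figure_id,
                              subfigure_id = directive$subfigure_id)
      if (length(parsed$diagnostics) > 0) {
        attr(rs, "diagnostics") <- c(attr(rs, "diagnostics"),
                                     parsed$diagnostics)
      }
      rs
    }, llps_error = function(e) {
      n_calls <<- n_calls + 1L
      rs <- record_set(origin = "extracted")
      attr(rs, "diagnostics") <- sprintf("figure %s failed: %s",
                                         directive$figure_id,
                                         conditionMessage(e))
      rs
    })
    out[[directive$figure_id]] <- rs
  }
  attr(out, "manifest") <- list(
    paper_id = bundle$paper_id, mode = "figure_by_figure",
    pattern = pattern, variant = variant, model_name = model_name,
    temperature = temperature, seed = seed, n_calls = n_calls,
    token_totals = as.list(tokens))
  out
}

#' Run single-shot (whole-paper) extraction
#'
#' Exactly one backend call over the PDF, with the filter criteria
#' prepended to the full prompt. Parsed records carry paper-level scope
#' (figure id missing).
#'
#' @inheritParams run_figure_by_figure
#' @return A paper-scoped [record_set] with a `"manifest"` attribute.
#' @export
run_single_shot <- function(bundle, blocks, backend,
                            rules = default_rules(), model_name = "mock",
                            temperature = 0, seed = NULL, retries = 3) {
  payload <- assemble_input(bundle, "pdf")
  prompt <- compose_single_shot_prompt(blocks)
  call <- backend_call(prompt, payload$attachments, model_name,
                       temperature, seed, tag = "paper")
  res <- retry_call(backend, call, retries)
  parsed <- parse_model_output(res$text)
  rs <- normalize_records(parsed$records, rules, paper_id = bundle$paper_id)
  if (length(parsed$diagnostics) > 0) {
    attr(rs, "diagnostics") <- c(attr(rs, "diagnostics"), parsed$diagnostics)
  }
  attr(rs, "manifest") <- list(
    paper_id = bundle$paper_id, mode = "single_shot", pattern = "pdf",
    model_name = model_name, temperature = temperature, seed = seed,
    n_calls = 1L, token_totals = res$token_counts)
  rs
}

# accepted model-output keys -> raw record field
OUTPUT_KEY_MAP <- c(
  protein_name = "protein_name", protein = "protein_name",
  protein_conc = "protein_conc", protein_concentration = "protein_conc",
  rna_conc = "rna_conc", rna_concentration = "rna_conc",
  ph = "ph", buffer_ph = "ph",
  temperature = "temperature", temp = "temperature",
  phase_status = "phase_status", phase = "phase_status",
  sequence_region = "sequence_region",
  modification_state = "modification_state"
)

#' Parse raw model output into records
#'
#' Total on text: extracts the first JSON array found (code fences
#' stripped), maps known keys onto record fields (unknown keys are
#' ignored and logged), skips objects carrying none of the six target
#' fields, and returns an empty result with a diagnostic for prose-only
#' responses.
#'
#' @param raw Model output text.
#' @return List: `records` (list of named lists, raw field values) and
#'   `diagnostics` (character).
#' @export
parse_model_output <- function(raw) {
  diags <- character(0)
  txt <- raw %||% ""
  txt <- gsub("```[a-zA-Z]*", "", txt)  # code fences are decoration
  arr_txt <- extract_json_array(txt)
  if (is.null(arr_txt)) {
    return(list(records = list(),
                diagnostics = "no JSON array found in model output"))
  }
  parsed <- tryCatch(jsonlite::fromJSON(arr_txt, simplifyVector = FALSE),
                     error = function(e) e)
  if (inherits(parsed, "error")) {
    return(list(records = list(), diagnostics = sprintf(
      "JSON array failed to parse: %s", conditionMessage(parsed))))
  }
  records <- list()
  for (i in seq_along(parsed)) {
    obj <- parsed[[i]]
    if (!is.list(obj) || is.null(names(obj))) {
      diags <- c(diags, sprintf("element %d is not an object; skipped", i))
      next
    }
    unknown <- setdiff(names(obj), names(OUTPUT_KEY_MAP))
    if (length(unknown) > 0) {
      diags <- c(diags, sprintf("element %d: ignored unknown key(s): %s",
                                i, paste(unknown, collapse = ", ")))
    }
    rec <- list()
    for (k in intersect(names(obj), names(OUTPUT_KEY_MAP))) {
      v <- obj[[k]]
      if (!is.null(v) && length(v) == 1 && !is.na(v)) {
        rec[[OUTPUT_KEY_MAP[[k]]]] <- v
      }
    }
    target_raw <- c("protein_name", "protein_conc", "rna_conc", "ph",
                    "temperature", "phase_status")
    if (!any(target_raw %in% names(rec))) {
      diags <- c(diags, sprintf(
        "element %d carries none of the six target fields; skipped", i))
      next
    }
    records[[length(records) + 1L]] <- rec
  }
  list(records = records, diagnostics = diags)
}

# first balanced top-level JSON array in the text, string-aware
extract_json_array <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  start <- NA_integer_
  depth <- 0L
  in_string <- FALSE
  escaped <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (in_string) {
      if (escaped) escaped <- FALSE
      else if (ch == "\\") escaped <- TRUE
      else if (ch == '"') in_string <- FALSE
      next
    }
    if (ch == '"') { in_string <- TRUE; next }
    if (ch == "[") {
      if (is.na(start)) start <- i
      depth <- depth + 1L
    } else if (ch == "]" && !is.na(start)) {
      depth <- depth - 1L
      if (depth == 0L) {
        return(paste(chars[start:i], collapse = ""))
      }
    }
  }
  NULL
}
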