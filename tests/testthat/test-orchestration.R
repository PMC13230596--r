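make_bundle <- function() {
  paper_bundle(
    "p1",
    figures = list(
      list(directive = figure_directive("f1"), image = "img/f1.png"),
      list(directive = figure_directive("f2"), image = "img/f2.png"),
      list(directive = figure_directive("f3"), image = "img/f3.png")),
    caption_method_text = "CAPTIONS AND METHODS",
    full_text = "FULL TEXT", pdf = "paper.pdf")
}

REC_JSON <- paste0(
  '[{"protein_name":"FUS","protein_conc":"5 uM","rna_conc":"0.1 uM",',
  '"ph":7.4,"temperature":"RT","phase_status":"droplets"}]')

test_that("payload assembly follows the input pattern exactly", {
  b <- make_bundle()
  d <- figure_directive("f2")
  p <- assemble_input(b, "figure", d)
  expect_identical(p$attachments[[1]],
                   list(kind = "image", path = "img/f2.png"))
  expect_null(p$inline_text)
  p <- assemble_input(b, "figure_cm", d)
  expect_identical(p$inline_text, "CAPTIONS AND METHODS")
  p <- assemble_input(b, "figure_fulltext", d)
  expect_identical(p$inline_text, "FULL TEXT")
  p <- assemble_input(b, "pdf")
  expect_identical(p$attachments[[1]],
                   list(kind = "pdf", path = "paper.pdf"))
})

test_that("missing bundle components fail before any backend call", {
  b <- paper_bundle("p1", figures = list(
    list(directive = figure_directive("f1"), image = "i.png")))
  expect_error(assemble_input(b, "pdf"), class = "llps_config_error")
  expect_error(assemble_input(b, "figure_cm", figure_directive("f1")),
               class = "llps_config_error")
  expect_error(assemble_input(b, "figure", figure_directive("f9")),
               "no image", class = "llps_config_error")
  expect_error(assemble_input(b, "figure"), class = "llps_config_error")
})

test_that("model output parsing is total on text", {
  out <- parse_model_output(paste0("Here you go:\n```json\n", REC_JSON,
                                   "\n```\nHope this helps!"))
  expect_length(out$records, 1)
  expect_identical(out$records[[1]]$protein_name, "FUS")

  out <- parse_model_output("No experiments were found in this figure.")
  expect_length(out$records, 0)
  expect_match(out$diagnostics, "no JSON array")

  # objects without any target field are skipped and logged
  out <- parse_model_output(
    '[{"sequence_region":"IDR"},{"protein_name":"fus","bogus_key":1}]')
  expect_length(out$records, 1)
  expect_match(paste(out$diagnostics, collapse = "; "), "none of the six")
  expect_match(paste(out$diagnostics, collapse = "; "), "bogus_key")

  # nested brackets inside strings do not break array extraction
  out <- parse_model_output(
    '[{"protein_name":"weird [x] name","ph":7}]')
  expect_identical(out$records[[1]]$protein_name, "weird [x] name")
})

test_that("figure-by-figure issues one call per figure, in order, isolating failures", {
  b <- make_bundle()
  backend <- mock_backend(list(
    f1 = REC_JSON,
    f2 = "utter garbage, no JSON here",
    f3 = REC_JSON))
  out <- run_figure_by_figure(b, "figure", default_prompt_blocks(),
                              "minimal_dk_guide", backend)
  expect_identical(names(out), c("f1", "f2", "f3"))
  expect_identical(backend_call_count(backend), 3L)
  expect_identical(attr(out, "manifest")$n_calls, 3L)
  expect_identical(nrow(out$f1), 1L)
  expect_identical(nrow(out$f2), 0L)
  expect_match(attr(out$f2, "diagnostics"), "no JSON array")
  expect_identical(out$f1$figure_id, "f1")
  expect_identical(out$f3$figure_id, "f3")
})

test_that("figure-by-figure runs are deterministic with a scripted backend", {
  b <- make_bundle()
  run <- function() {
    out <- run_figure_by_figure(b, "figure_cm", default_prompt_blocks(),
                                "minimal_dk", mock_backend(list(
                                  f1 = REC_JSON, f2 = REC_JSON,
                                  f3 = "[]")))
    lapply(out, as.data.frame)
  }
  expect_identical(run(), run())
})

test_that("single-shot issues exactly one paper-scoped call with the filter prompt", {
  b <- make_bundle()
  backend <- mock_backend(list(paper = paste0(
    '[{"protein_name":"a","ph":7},{"protein_name":"b","ph":7},',
    '{"protein_name":"c","ph":7},{"protein_name":"d","ph":7},',
    '{"protein_name":"e","ph":7}]')))
  rs <- run_single_shot(b, default_prompt_blocks(), backend)
  expect_identical(backend_call_count(backend), 1L)
  expect_identical(nrow(rs), 5L)
  expect_true(all(is.na(rs$figure_id)))
  expect_identical(unique(rs$paper_id), "p1")
  seen <- attr(backend, "env")$calls[[1]]
  expect_match(seen$prompt, "single type of protein")  # filter block present
  expect_identical(seen$attachments[[1]]$kind, "pdf")

  empty_backend <- mock_backend(list(paper = "nothing to report"))
  rs <- run_single_shot(b, default_prompt_blocks(), empty_backend)
  expect_identical(nrow(rs), 0L)
  expect_match(attr(rs, "diagnostics"), "no JSON array")
})

test_that("transport errors are retried; content errors are not", {
  b <- make_bundle()
  env <- new.env(); env$n <- 0L
  flaky <- function(call) {
    env$n <- env$n + 1L
    if (env$n <= 2) llpsie:::llps_transport_error("connection reset")
    backend_response(REC_JSON)
  }
  out <- run_figure_by_figure(
    paper_bundle("p1", b$figures[1]), "figure",
    default_prompt_blocks(), "minimal", flaky)
  expect_identical(nrow(out$f1), 1L)
  expect_identical(env$n, 3L)

  env$n <- 0L
  always_down <- function(call) {
    env$n <- env$n + 1L
    llpsie:::llps_transport_error("connection reset")
  }
  out <- run_figure_by_figure(
    paper_bundle("p1", b$figures[1]), "figure",
    default_prompt_blocks(), "minimal", always_down, retries = 3)
  expect_identical(env$n, 4L)  # initial + 3 retries, then isolated
  expect_identical(nrow(out$f1), 0L)
  expect_match(attr(out$f1, "diagnostics"), "connection reset")
})
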