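# Subprocess adapters.  RDKit (structure handling, Morgan bits, 2D
# descriptors) and scikit-learn (RF/SVM fitting) are reached through small
# worker scripts shipped in inst/python/, exchanging JSON on disk.  Nothing
# scientific happens over there that this package's contracts depend on
# beyond the delegated learner/toolkit internals themselves.

python_binary <- function() {
  bin <- Sys.getenv("BBBFP_PYTHON", "python")
  path <- Sys.which(bin)
  if (!nzchar(path))
    abort_input("python interpreter '", bin, "' not found on PATH; ",
                "set BBBFP_PYTHON or install python with rdkit/scikit-learn")
  unname(path)
}

python_worker <- function(name) {
  p <- system.file("python", name, package = "bbbfp")
  if (!nzchar(p)) {
    # during development (pkgload) inst/ may not be installed yet
    p <- file.path("inst", "python", name)
  }
  assert_that(file.exists(p), paste0("worker script ", name, " not found"))
  normalizePath(p)
}

# Run a worker command: writes `request` as JSON, invokes
#   python <worker> <command> <request.json> <response.json>
# and parses the response.  Raises the worker's error message on failure.
run_python_worker <- function(worker, command, request) {
  req <- tempfile(fileext = ".json")
  res <- tempfile(fileext = ".json")
  on.exit(unlink(c(req, res)), add = TRUE)
  write_json_file(request, req)
  out <- suppressWarnings(system2(python_binary(),
                                  c(python_worker(worker), command, req, res),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L || !file.exists(res))
    abort_input("python worker '", worker, " ", command, "' failed: ",
                paste(out, collapse = "\n"))
  jsonlite::read_json(res, simplifyVector = TRUE)
}

chem_worker <- function(command, request) {
  run_python_worker("chem.py", command, request)
}

learner_worker <- function(command, request) {
  run_python_worker("learners.py", command, request)
}
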