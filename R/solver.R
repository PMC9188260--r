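#' @keywords internal
#' @noRd
.solver <- new.env(parent = emptyenv())

#' Locate the python interpreter used by the HiGHS solver backend
#'
#' The LP/MILP backend delegates to the HiGHS solver through a small python
#' helper (scipy). The interpreter is resolved from, in order: the
#' `lpmgem.python` option, the `LPMGEM_PYTHON` environment variable, then
#' `python`/`python3` on the PATH.
#' @return Path to a python executable.
#' @keywords internal
solver_python <- function() {
  cand <- c(
    getOption("lpmgem.python", ""),
    Sys.getenv("LPMGEM_PYTHON", ""),
    Sys.which("python"),
    Sys.which("python3")
  )
  cand <- cand[nzchar(cand)]
  if (length(cand) == 0L) {
    stop("no python interpreter found for the LP solver backend", call. = FALSE)
  }
  cand[[1L]]
}

solver_script <- function() {
  path <- system.file("python", "lp_server.py", package = "lpmgem")
  if (!nzchar(path)) stop("lp_server.py not found in package installation")
  path
}

#' Build a linear or mixed-integer program for the solver backend
#'
#' A light container following the solver abstraction used throughout the
#' package: minimize (or maximize) `obj %*% x` subject to
#' `A_eq %*% x == b_eq`, `A_ub %*% x <= b_ub` and `lb <= x <= ub`, with
#' optional integrality (0 = continuous, 1 = integer/binary via unit bounds).
#'
#' @param obj Objective coefficient vector.
#' @param lb,ub Variable bounds; `Inf`/`-Inf` allowed.
#' @param A_eq,b_eq Equality constraint matrix/rhs (or `NULL`).
#' @param A_ub,b_ub Inequality (`<=`) constraint matrix/rhs (or `NULL`).
#' @param integrality Integer vector (0/1) per variable, or `NULL`.
#' @param maximize Maximize instead of minimize.
#' @return An object of class `lpm_lp`.
#' @keywords internal
lp_problem <- function(obj, lb, ub, A_eq = NULL, b_eq = NULL,
                       A_ub = NULL, b_ub = NULL, integrality = NULL,
                       maximize = FALSE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (!is.null(A_eq)) {
    A_eq <- matrix(as.numeric(A_eq), ncol = n)
    stopifnot(nrow(A_eq) == length(b_eq))
    if (nrow(A_eq) == 0L) A_eq <- b_eq <- NULL
  }
  if (!is.null(A_ub)) {
    A_ub <- matrix(as.numeric(A_ub), ncol = n)
    stopifnot(nrow(A_ub) == length(b_ub))
    if (nrow(A_ub) == 0L) A_ub <- b_ub <- NULL
  }
  structure(
    list(
      obj = as.numeric(obj), lb = as.numeric(lb), ub = as.numeric(ub),
      A_eq = A_eq, b_eq = as.numeric(b_eq),
      A_ub = A_ub, b_ub = as.numeric(b_ub),
      integrality = if (!is.null(integrality)) as.integer(integrality),
      maximize = isTRUE(maximize)
    ),
    class = "lpm_lp"
  )
}

.finite_cap <- function(x) {
  x[x == Inf] <- 1e30
  x[x == -Inf] <- -1e30
  x
}

.encode_problem <- function(p) {
  out <- list(
    obj = .finite_cap(p$obj),
    lb = .finite_cap(p$lb),
    ub = .finite_cap(p$ub),
    maximize = p$maximize
  )
  if (!is.null(p$A_eq)) {
    out$A_eq <- p$A_eq
    out$b_eq <- p$b_eq
  }
  if (!is.null(p$A_ub)) {
    out$A_ub <- p$A_ub
    out$b_ub <- p$b_ub
  }
  if (!is.null(p$integrality) && any(p$integrality > 0L)) {
    out$integrality <- p$integrality
  }
  out
}

solver_start <- function() {
  if (!is.null(.solver$con)) return(invisible(TRUE))
  if (isTRUE(.solver$oneshot)) return(invisible(FALSE))
  portfile <- tempfile("lpm_port_")
  errfile <- tempfile("lpm_err_")
  ok <- tryCatch({
    system2(solver_python(), c(shQuote(solver_script()), "--serve"),
            stdout = portfile, stderr = errfile, wait = FALSE)
    line <- ""
    for (i in seq_len(600L)) {        # wait up to 60 s for interpreter start
      if (file.exists(portfile)) {
        line <- tryCatch(readLines(portfile, n = 1L, warn = FALSE),
                         error = function(e) character())
        if (length(line) && grepl("^PORT ", line)) break
      }
      Sys.sleep(0.1)
    }
    if (!length(line) || !grepl("^PORT ", line)) {
      stop("solver server did not start: ",
           paste(readLines(errfile, warn = FALSE), collapse = " "))
    }
    parts <- strsplit(line, " ", fixed = TRUE)[[1L]]
    port <- as.integer(parts[[2L]])
    token <- parts[[4L]]
    con <- socketConnection("127.0.0.1", port = port, blocking = TRUE,
                            open = "r+", timeout = 1800)
    .solver$con <- con
    .solver$token <- token
    TRUE
  }, error = function(e) {
    warning("falling back to one-shot solver subprocesses: ",
            conditionMessage(e), call. = FALSE)
    .solver$oneshot <- TRUE
    FALSE
  })
  invisible(ok)
}

#' Stop the background solver process
#'
#' Safe to call at any time; the server restarts lazily on the next solve.
#' @return Invisibly `TRUE`.
#' @export
solver_stop <- function() {
  if (!is.null(.solver$con)) {
    try({
      writeLines('{"quit": true}', .solver$con)
      flush(.solver$con)
    }, silent = TRUE)
    try(close(.solver$con), silent = TRUE)
    .solver$con <- NULL
    .solver$token <- NULL
  }
  invisible(TRUE)
}

.solver_request <- function(req_json) {
  writeLines(req_json, .solver$con)
  flush(.solver$con)
  resp <- readLines(.solver$con, n = 1L, warn = FALSE)
  if (length(resp) == 0L) stop("solver server closed the connection")
  resp
}

.solve_oneshot <- function(req_json) {
  fin <- tempfile("lpm_req_", fileext = ".json")
  fout <- tempfile("lpm_res_", fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(req_json, fin)
  status <- system2(solver_python(),
                    c(shQuote(solver_script()), "--oneshot",
                      shQuote(fin), shQuote(fout)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(fout)) {
    stop("one-shot solver subprocess failed (exit ", status, ")")
  }
  paste(readLines(fout, warn = FALSE), collapse = "")
}

#' Solve a batch of LP/MILP problems with the HiGHS backend
#'
#' Problems are independent; batching them into one request amortizes the
#' round-trip to the solver process (important for FVA, which issues two LPs
#' per reaction).
#'
#' @param problems List of [lp_problem()] objects.
#' @return List of results: `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`, ...), `objective`, `x` (primal values or `NULL`).
#' @keywords internal
solve_lp_batch <- function(problems) {
  stopifnot(is.list(problems), length(problems) > 0L)
  payload <- list(problems = lapply(problems, .encode_problem))
  server <- solver_start()
  if (server) payload$token <- .solver$token
  req_json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                               null = "null")
  resp <- if (server) {
    tryCatch(.solver_request(req_json), error = function(e) {
      solver_stop()
      .solver$oneshot <- TRUE
      .solve_oneshot(req_json)
    })
  } else {
    .solve_oneshot(req_json)
  }
  parsed <- jsonlite::fromJSON(resp, simplifyVector = FALSE)
  if (!is.null(parsed$error)) stop("solver backend error: ", parsed$error)
  lapply(parsed$results, function(r) {
    list(
      status = r$status,
      objective = if (!is.null(r$objective)) as.numeric(r$objective),
      x = if (!is.null(r$x)) vapply(r$x, as.numeric, numeric(1)),
      message = r$message
    )
  })
}

solve_lp <- function(problem) solve_lp_batch(list(problem))[[1L]]

.onUnload <- function(libpath) {
  solver_stop()
}
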