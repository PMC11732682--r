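# Internal helpers shared across modules.

# Classed conditions so the CLI can map failures onto exit codes
# (usage errors -> 2, data errors -> 3).
stopUsage <- function(...) {
  stop(structure(class = c("usageError", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stopData <- function(...) {
  stop(structure(class = c("dataError", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. Keeps every generator reproducible without
# clobbering the session RNG.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Cache of voxel-centre coordinate grids (m x 3 matrices of 1-based indices),
# keyed by the grid dimensions; rebuilt grids dominate warp cost otherwise.
.grid_cache <- new.env(parent = emptyenv())

gridCoords <- function(dims) {
  key <- paste(dims, collapse = "x")
  g <- .grid_cache[[key]]
  if (is.null(g)) {
    nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
    g <- cbind(rep.int(seq_len(nx), ny * nz),
               rep.int(rep(seq_len(ny), each = nx), nz),
               rep(seq_len(nz), each = nx * ny))
    storage.mode(g) <- "double"
    .grid_cache[[key]] <- g
  }
  g
}

# Instrumentation counters used by tests to assert that accumulation warps
# the original moving image exactly once per cascade and that the training
# loss touches only the final outputs.
.instr <- new.env(parent = emptyenv())
.instr$warp_calls <- 0L
.instr$loss_evals <- 0L

resetInstrumentation <- function() {
  .instr$warp_calls <- 0L
  .instr$loss_evals <- 0L
  invisible(NULL)
}

bumpWarpCount <- function() .instr$warp_calls <- .instr$warp_calls + 1L
bumpLossCount <- function() .instr$loss_evals <- .instr$loss_evals + 1L

getInstrumentation <- function() {
  list(warp_calls = .instr$warp_calls, loss_evals = .instr$loss_evals)
}

assertOdd <- function(d, what = "window size") {
  if (any(d %% 2 != 1) || any(d < 3))
    stopUsage(what, " must be odd and >= 3, got ", paste(d, collapse = ", "))
}

sameDim3 <- function(a, b) identical(dim(a)[1:3], dim(b)[1:3])
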