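## Shared internal helpers: classed errors, seed derivation, small utilities.

halopan_error <- function(msg, class = "halopan_input_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "halopan_error", "error", "condition")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Derive a stage-specific seed from a master seed, kept well inside the
## 32-bit integer range.  All randomness in the package funnels through
## seeds produced here so that one master seed fixes every stage.
stage_seed <- function(seed, stage) {
  offsets <- c(
    tree = 101L, content = 211L, proteomes = 307L, qc = 401L,
    hits = 503L, mcl = 601L, curves = 701L, boot = 809L,
    pantree = 907L, asr = 1009L, eval = 1103L, calibration = 1201L
  )
  off <- offsets[[stage]]
  if (is.null(off)) halopan_error(paste0("unknown stage: ", stage))
  (as.integer(seed) %% 2000000000L) + off
}

## Truncate (floor) to one decimal; the convention used for reported
## ancestral/derived percentages (so a 44.84/55.16 split prints 44.8/55.1).
trunc1 <- function(x) floor(x * 10 + 1e-9) / 10

## All permutations of a vector (small n only).
all_permutations <- function(v) {
  n <- length(v)
  if (n > 8L) halopan_error("refusing to enumerate permutations for n > 8")
  if (n <= 1L) return(list(v))
  out <- vector("list", factorial(n))
  k <- 0L
  for (i in seq_len(n)) {
    for (p in all_permutations(v[-i])) {
      k <- k + 1L
      out[[k]] <- c(v[i], p)
    }
  }
  out
}

## Name a tree node: tip label for tips, "n<id>" for internal nodes (or the
## existing node label when present).
node_name <- function(tree, i) {
  nt <- length(tree$tip.label)
  if (i <= nt) return(tree$tip.label[i])
  lab <- tree$node.label[i - nt]
  if (!is.null(lab) && length(lab) == 1L && !is.na(lab) && nzchar(lab)) lab
  else paste0("n", i)
}

node_names <- function(tree) {
  vapply(seq_len(length(tree$tip.label) + tree$Nnode),
         function(i) node_name(tree, i), character(1))
}
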