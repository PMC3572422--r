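# Parametric read simulator: i.i.d. per-position errors at rate rho, split
# into substitutions / insertions / deletions, which induces geometric
# error-free run lengths.  Ground-truth coordinates are recorded for
# mapping-accuracy evaluation.

#' Simulation configuration
#'
#' @param rho per-base error probability in `[0, 1)`.
#' @param mix length-3 error-type mix `(substitution, insertion, deletion)`
#'   summing to 1; default `c(0.10, 0.62, 0.28)`.
#' @param read_length target read length (every read is emitted at exactly
#'   this length).
#' @param n_reads number of reads.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(rho = 0.15, mix = c(sub = 0.10, ins = 0.62, del = 0.28),
                       read_length = 1000, n_reads = 100, seed = 1L) {
  stopifnot(rho >= 0, rho < 1, length(mix) == 3,
            abs(sum(mix) - 1) < 1e-8, read_length >= 1, n_reads >= 0)
  structure(list(rho = rho, mix = mix, read_length = read_length,
                 n_reads = n_reads, seed = as.integer(seed)),
            class = "sim_config")
}

#' Random genome
#'
#' I.i.d. bases at the given GC fraction; deterministic per seed.
#'
#' @param length genome length (>= 1).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed integer seed.
#' @param id sequence id.
#' @return a [seq_record()].
#' @export
random_genome <- function(length, gc = 0.5, seed = 1L, id = "ref") {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq_record(id, paste(sample(names(p), length, replace = TRUE, prob = p),
                       collapse = ""))
}

#' Simulate error-corrupted reads
#'
#' Each read samples a uniform start and strand, then scans the template:
#' every position errs independently with probability `rho`, the error
#' type drawn from `mix`.  An insertion emits a random extra base without
#' consuming template; a deletion consumes without emitting; a substitution
#' emits a random different base.  Emission stops once `read_length` bases
#' have been produced; the consumed template span is the truth interval.
#' Flat quality tracks consistent with `rho` and `mix` are attached
#' (e.g. the insertion track is `-10*log10(rho * mix_ins)`), with random
#' alternative calls.
#'
#' @param genome a [seq_record()].
#' @param cfg a [sim_config()].
#' @return list of `sim_read`s: `record` (a [seq_record()]) and `truth`
#'   (`ref`, `strand`, `start`, `end`; 0-based half-open, forward genome).
#' @export
simulate_reads <- function(genome, cfg = sim_config()) {
  stopifnot(inherits(genome, "seq_record"), inherits(cfg, "sim_config"))
  G <- nchar(genome$seq)
  Lr <- cfg$read_length
  max_span <- ceiling(Lr * (1 + 2 * cfg$rho)) + 10L
  if (G <= max_span) stop("genome shorter than the maximum read span")
  set.seed(cfg$seed)
  fwd <- genome$seq
  rev <- revcomp(genome$seq)
  qv_template <- flat_qv(cfg)
  lapply(seq_len(cfg$n_reads), function(i) {
    strand <- sample(c("+", "-"), 1L)
    start0 <- sample.int(G - max_span, 1L) - 1L # 0-based on chosen strand
    tmpl <- substr(if (strand == "+") fwd else rev,
                   start0 + 1L, start0 + max_span)
    em <- corrupt_template(tmpl, Lr, cfg)
    # truth on the forward genome, 0-based half-open
    if (strand == "+") {
      tstart <- start0; tend <- start0 + em$consumed
    } else {
      tend <- G - start0; tstart <- G - (start0 + em$consumed)
    }
    qv <- quality_arrays(rep(qv_template$ins, Lr), rep(qv_template$sub, Lr),
                         rep(qv_template$del, Lr),
                         sample(c("A", "C", "G", "T"), Lr, replace = TRUE),
                         sample(c("A", "C", "G", "T"), Lr, replace = TRUE))
    structure(list(record = seq_record(sprintf("read%05d", i), em$seq, qv),
                   truth = list(ref = genome$id, strand = strand,
                                start = tstart, end = tend),
                   events = em$events),
              class = "sim_read")
  })
}

flat_qv <- function(cfg) {
  ph <- function(p) if (p <= 0) 93 else min(93, round(-10 * log10(p)))
  list(ins = ph(cfg$rho * cfg$mix[2]), sub = ph(cfg$rho * cfg$mix[1]),
       del = ph(cfg$rho * cfg$mix[3]))
}

# scan one template, emitting until `target` bases are produced
corrupt_template <- function(tmpl, target, cfg) {
  bases <- c("A", "C", "G", "T")
  tv <- strsplit(tmpl, "", fixed = TRUE)[[1]]
  out <- character(target)
  n_out <- 0L
  t <- 1L
  ev <- c(sub = 0L, ins = 0L, del = 0L)
  while (n_out < target) {
    if (t > length(tv)) stop("template exhausted; increase the span margin")
    if (cfg$rho > 0 && runif(1) < cfg$rho) {
      type <- sample.int(3L, 1L, prob = cfg$mix) # 1 sub, 2 ins, 3 del
      ev[type] <- ev[type] + 1L
      if (type == 1L) {
        n_out <- n_out + 1L
        out[n_out] <- sample(setdiff(bases, tv[t]), 1L)
        t <- t + 1L
      } else if (type == 2L) {
        n_out <- n_out + 1L
        out[n_out] <- sample(bases, 1L)
        # template position not consumed; it is revisited
      } else {
        t <- t + 1L
      }
    } else {
      n_out <- n_out + 1L
      out[n_out] <- tv[t]
      t <- t + 1L
    }
  }
  list(seq = paste(out, collapse = ""), consumed = t - 1L, events = ev)
}

#' Phred-scale mapping accuracy against simulated truth
#'
#' A read is correct when it is mapped, the strand matches, and the mapped
#' genome start is within `slack` bases of the truth start.  Returns
#' `-10*log10((missing + mismapped) / total)`; with no wrong reads the
#' value is capped at `-10*log10(0.5 / total)` (fewer than half an error).
#'
#' @param results list of mapping results from [map_reads()].
#' @param truths list of truth entries (`ref`, `strand`, `start`, `end`),
#'   aligned with `results` (e.g. `lapply(sim_reads, `[[`, "truth")`).
#' @param slack coordinate tolerance in bases (default 50).
#' @return list with `phred`, `n_correct`, `n_wrong`, `total`.
#' @export
mapability_phred <- function(results, truths, slack = 50) {
  stopifnot(length(results) == length(truths), length(results) >= 1)
  correct <- mapply(function(res, tr) {
    isTRUE(res$mapped) && res$ref_id == tr$ref && res$strand == tr$strand &&
      abs(res$genome_start - tr$start) <= slack
  }, results, truths)
  total <- length(results)
  wrong <- total - sum(correct)
  phred <- if (wrong == 0) -10 * log10(0.5 / total)
           else -10 * log10(wrong / total)
  list(phred = phred, n_correct = sum(correct), n_wrong = wrong,
       total = total)
}
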