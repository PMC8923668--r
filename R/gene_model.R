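#' Gene model with smFISH probe layout
#'
#' Represents the transcribed gene as a template of `transcript_length_nt`
#' nucleotides carrying an ordered set of probe binding positions. A Pol II
#' that has reached transcript coordinate `x` has synthesized the binding
#' sites of all probes with position `<= x`; nascent fluorescence is the
#' probe count normalized to the number of probes on a finished mRNA, i.e.
#' expressed in cytoplasmic units (C.U.).
#'
#' @param transcript_length_nt positive integer, length of the mature
#'   transcript in nucleotides.
#' @param probe_positions_nt strictly increasing numeric vector of transcript
#'   coordinates in `[1, transcript_length_nt]`, one per probe.
#' @return An object of class `gene_model` with fields
#'   `transcript_length_nt`, `probe_positions_nt` and `n_probes`.
#' @examples
#' g <- gene_model(4500, c(1000, 2000, 3000, 4000))
#' nascent_signal(c(2500, 4500), g)
#' @export
gene_model <- function(transcript_length_nt, probe_positions_nt) {
  if (!is.numeric(transcript_length_nt) || length(transcript_length_nt) != 1 ||
      transcript_length_nt < 1) {
    stop("`transcript_length_nt` must be a single positive number")
  }
  p <- as.numeric(probe_positions_nt)
  if (length(p) < 1 || any(!is.finite(p))) {
    stop("`probe_positions_nt` must be a non-empty finite numeric vector")
  }
  if (any(diff(p) <= 0)) {
    stop("`probe_positions_nt` must be strictly increasing")
  }
  if (p[1] < 1 || p[length(p)] > transcript_length_nt) {
    stop("probe positions must lie in [1, transcript_length_nt]")
  }
  structure(
    list(
      transcript_length_nt = as.numeric(transcript_length_nt),
      probe_positions_nt = p,
      n_probes = length(p)
    ),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %d nt, %d probes (first %g, last %g)\n",
              as.integer(x$transcript_length_nt), x$n_probes,
              x$probe_positions_nt[1],
              x$probe_positions_nt[x$n_probes]))
  invisible(x)
}

#' Uniformly spaced probe set
#'
#' Builds a [gene_model] with `n_probes` probes evenly spaced across the
#' transcript: probe i sits at `i * transcript_length_nt / n_probes`. The
#' default gene used throughout the package emulates a 4500-nt transcript
#' tiled by 67 exonic probes; only the relative probe layout matters for the
#' C.U. rendering, since all probes bind exonic sequence.
#'
#' @param n_probes integer >= 1.
#' @param transcript_length_nt integer >= `n_probes`.
#' @return A [gene_model].
#' @examples
#' make_uniform_gene(4, 400)$probe_positions_nt  # 100 200 300 400
#' @export
make_uniform_gene <- function(n_probes, transcript_length_nt) {
  if (!is.numeric(n_probes) || length(n_probes) != 1 || n_probes < 1) {
    stop("`n_probes` must be a single integer >= 1")
  }
  if (!is.numeric(transcript_length_nt) || length(transcript_length_nt) != 1 ||
      transcript_length_nt < n_probes) {
    stop("`transcript_length_nt` must be >= `n_probes`")
  }
  pos <- seq_len(n_probes) * transcript_length_nt / n_probes
  gene_model(transcript_length_nt, pos)
}

#' Default synthetic gene (67 probes on 4500 nt)
#'
#' @return A [gene_model] with 67 uniformly spaced probes on a 4500-nt
#'   transcript.
#' @export
default_gene <- function() make_uniform_gene(67L, 4500L)

#' Nascent fluorescence of a set of Pol II positions
#'
#' Converts Pol II positions on the gene body into nascent-transcript signal
#' in cytoplasmic units: each Pol II contributes the number of probe binding
#' sites already transcribed (probes with position `<=` the Pol II position),
#' normalized to the total probe count. A Pol II at or past the last probe
#' contributes exactly 1 C.U.; an empty position set gives 0.
#'
#' @param polii_positions numeric vector of transcript coordinates in
#'   `[0, transcript_length_nt]` (may be empty).
#' @param gene a [gene_model].
#' @return Non-negative scalar, nascent activity in C.U.
#' @export
nascent_signal <- function(polii_positions, gene) {
  stopifnot(inherits(gene, "gene_model"))
  if (length(polii_positions) == 0) return(0)
  pos <- as.numeric(polii_positions)
  if (any(!is.finite(pos)) || any(pos < 0) ||
      any(pos > gene$transcript_length_nt)) {
    stop("invalid simulator state: Pol II position outside [0, gene length]")
  }
  counts <- findInterval(pos, gene$probe_positions_nt)
  sum(counts) / gene$n_probes
}

#' Serialize / deserialize a gene model as JSON
#'
#' @param gene a [gene_model].
#' @param path file path.
#' @return `read_gene_model` returns a [gene_model]; `write_gene_model`
#'   returns `path` invisibly.
#' @export
write_gene_model <- function(gene, path) {
  stopifnot(inherits(gene, "gene_model"))
  jsonlite::write_json(unclass(gene), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gene_model
#' @export
read_gene_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gene_model(x$transcript_length_nt, x$probe_positions_nt)
}
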