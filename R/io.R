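#' Write and read spike records
#'
#' Spike events are `(step k, logical neuron id, node id)` records. The text
#' format is one line per spike, `"t_ms neuron_id"` with `t_ms = k * h`
#' printed to one decimal. The binary format packs each record into 64 bits —
#' node id in bits 63-48, step `k` in bits 47-16, neuron id in bits 15-0 —
#' stored little-endian; records round-trip bit-exactly.
#'
#' @param records tibble with columns `k` and `neuron` (and optionally
#'   `node`, default 0), e.g. the `spikes` element of an `izh_sim`.
#' @param path file path.
#' @param format `"text"` or `"binary"`.
#' @param h step size in ms (used to convert between `k` and `t_ms`).
#' @return `write_spikes()` returns `path` invisibly; `read_spikes()` a
#'   tibble `k, neuron, node, t_ms` in file order.
#' @examples
#' f <- tempfile()
#' write_spikes(tibble::tibble(k = 10L, neuron = 7L), f)
#' readLines(f)
#' read_spikes(f)
#' @export
write_spikes <- function(records, path, format = c("text", "binary"),
                         h = 0.1) {
  format <- match.arg(format)
  k <- as.numeric(records$k)
  neuron <- as.numeric(records$neuron)
  node <- if ("node" %in% names(records)) as.numeric(records$node) else 0
  node <- rep_len(node, length(k))
  if (format == "text") {
    writeLines(sprintf("%.1f %d", k * h, as.integer(neuron)), path)
  } else {
    stopifnot(all(neuron >= 0 & neuron < 2^16), all(k >= 0 & k < 2^32),
              all(node >= 0 & node < 2^16))
    n <- length(k)
    bytes <- matrix(0L, nrow = 8, ncol = n)
    bytes[1, ] <- neuron %% 256; bytes[2, ] <- neuron %/% 256
    for (i in 0:3) bytes[3 + i, ] <- (k %/% 256^i) %% 256
    bytes[7, ] <- node %% 256; bytes[8, ] <- node %/% 256
    writeBin(as.raw(as.vector(bytes)), path)
  }
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path, format = c("text", "binary"), h = 0.1) {
  format <- match.arg(format)
  if (format == "text") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) {
      return(tibble::tibble(k = integer(), neuron = integer(),
                            node = integer(), t_ms = numeric()))
    }
    parts <- strsplit(trimws(lines), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) != 2)
    if (length(bad) > 0)
      stop("malformed spike record at line ", bad[1], " of ", path)
    t_ms <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
    neuron <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
    bad <- which(is.na(t_ms) | is.na(neuron))
    if (length(bad) > 0)
      stop("malformed spike record at line ", bad[1], " of ", path)
    tibble::tibble(k = as.integer(round(t_ms / h)), neuron = neuron,
                   node = 0L, t_ms = t_ms)
  } else {
    bytes <- readBin(path, "raw", n = file.size(path))
    if (length(bytes) %% 8 != 0) stop("malformed binary spike file: ", path)
    m <- matrix(as.numeric(bytes), nrow = 8)
    neuron <- m[1, ] + 256 * m[2, ]
    k <- m[3, ] + 256 * m[4, ] + 256^2 * m[5, ] + 256^3 * m[6, ]
    node <- m[7, ] + 256 * m[8, ]
    tibble::tibble(k = as.integer(k), neuron = as.integer(neuron),
                   node = as.integer(node), t_ms = k * h)
  }
}

#' Write and read network description files
#'
#' A network directory holds `neurons.csv` (`id,model,a,b,c,d,v0,u0`) and
#' `connections.csv` (`source,target,weight_pA,delay_ms`).
#'
#' @param net an `izh_net`.
#' @param dir directory (created if needed).
#' @param config a [node_config()] used when rebuilding the network.
#' @return `write_network()` returns `dir` invisibly; `read_network()` an
#'   `izh_net`.
#' @export
write_network <- function(net, dir) {
  stopifnot(inherits(net, "izh_net"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(neurons(net), file.path(dir, "neurons.csv"))
  cn <- connections(net)[, c("source", "target", "weight_pA", "delay_ms")]
  readr::write_csv(cn, file.path(dir, "connections.csv"))
  invisible(dir)
}

#' @rdname write_network
#' @export
read_network <- function(dir, config = node_config()) {
  nt <- readr::read_csv(file.path(dir, "neurons.csv"),
                        show_col_types = FALSE)
  cn <- readr::read_csv(file.path(dir, "connections.csv"),
                        show_col_types = FALSE)
  net <- new_network(config)
  net <- net_create(net, nt$id,
                    tibble::tibble(model = nt$model, a = nt$a, b = nt$b,
                                   c = nt$c, d = nt$d),
                    v0 = nt$v0, u0 = nt$u0)
  if (nrow(cn) > 0)
    net <- net_connect(net, cn$source, cn$target, cn$weight_pA, cn$delay_ms)
  net
}

#' Write and read a simulation configuration file
#'
#' JSON key/value file mirroring the node configuration, stimulus and seed.
#'
#' @param config a [node_config()].
#' @param stimulus a [stim_spec()].
#' @param k_steps steps to simulate.
#' @param arithmetic arithmetic mode.
#' @param path file path.
#' @return `read_sim_config()`: list with `config`, `stimulus`, `k_steps`,
#'   `arithmetic`.
#' @export
write_sim_config <- function(path, config = node_config(),
                             stimulus = stim_spec(), k_steps = 1000L,
                             arithmetic = "fixed") {
  jsonlite::write_json(
    list(config = unclass(config), stimulus = unclass(stimulus),
         k_steps = k_steps, arithmetic = arithmetic),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- x$config
  list(config = node_config(P = cfg$P, N_P = cfg$N_P, DS = cfg$DS,
                            K_RB = cfg$K_RB, h = cfg$h, d_min = cfg$d_min,
                            c_cap = cfg$c_cap),
       stimulus = stim_spec(i_ext = x$stimulus$i_ext,
                            pulse_amplitude = x$stimulus$pulse_amplitude,
                            pulse_targets = x$stimulus$pulse_targets,
                            seed = x$stimulus$seed),
       k_steps = as.integer(x$k_steps),
       arithmetic = x$arithmetic)
}
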