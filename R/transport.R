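#' Wire frame format and transports
#'
#' Every protocol message is a framed sequence of serialized field elements:
#' a 4-byte magic (`MPCQ`), a 16-byte session id, an 8-byte big-endian
#' sequence number per sender, a 1-byte opcode, a 4-byte big-endian element
#' count and the payload of fixed-width big-endian field elements. The
#' in-process and socket transports move byte-identical frames; the framing
#' layer is what the communication ledger measures.
#'
#' @name transport
NULL

FRAME_MAGIC <- as.raw(c(0x4D, 0x50, 0x43, 0x51)) # "MPCQ"
FRAME_HEADER_BYTES <- 33L
OP_OPEN <- 0x01

uint_to_raw <- function(x, width) {
  out <- raw(width)
  for (i in seq_len(width)) {
    out[width - i + 1L] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

raw_to_uint <- function(r) {
  sum(as.numeric(r) * 256^(rev(seq_along(r)) - 1))
}

frame_encode <- function(session_id, seq, opcode, values_hex, width) {
  c(
    FRAME_MAGIC,
    session_id,
    uint_to_raw(seq, 8L),
    as.raw(opcode),
    uint_to_raw(length(values_hex), 4L),
    fp_to_raw_cpp(values_hex, width)
  )
}

frame_decode <- function(bytes, width) {
  stopifnot(length(bytes) >= FRAME_HEADER_BYTES)
  if (!identical(bytes[1:4], FRAME_MAGIC)) stop("bad frame magic", call. = FALSE)
  count <- raw_to_uint(bytes[30:33])
  payload <- bytes[-seq_len(FRAME_HEADER_BYTES)]
  stopifnot(length(payload) == count * width)
  list(
    session_id = bytes[5:20],
    seq = raw_to_uint(bytes[21:28]),
    opcode = as.integer(bytes[29]),
    values = if (count == 0) character(0) else fp_from_raw_cpp(payload, width)
  )
}

# transports -----------------------------------------------------------------
# A transport delivers a list of addressed frames (from, to, bytes) and
# returns them as received. In-process delivery is a hand-over; the socket
# transport pushes every frame through a real loopback TCP connection, so
# the bytes cross the OS network stack.

inproc_transport <- function() {
  structure(
    list(
      type = "inproc",
      deliver = function(frames) frames,
      close = function() invisible(NULL)
    ),
    class = "mpc_transport"
  )
}

socket_transport <- function(tries = 20L) {
  srv <- NULL
  port <- NA_integer_
  for (i in seq_len(tries)) {
    port <- sample(49152:65535, 1L)
    srv <- tryCatch(serverSocket(port), error = function(e) NULL)
    if (!is.null(srv)) break
  }
  if (is.null(srv)) stop("could not bind a loopback port", call. = FALSE)
  cl <- socketConnection("127.0.0.1",
    port = port, blocking = TRUE,
    open = "a+b", timeout = 30
  )
  peer <- socketAccept(srv, blocking = TRUE, open = "a+b", timeout = 30)
  close(srv)
  chunked_send <- function(wconn, rconn, bytes) {
    # bounded chunks with an immediate drain so the loopback buffers
    # never fill in a single-process run
    got <- raw(0)
    off <- 0L
    total <- length(bytes)
    while (off < total) {
      take <- min(16384L, total - off)
      writeBin(bytes[(off + 1L):(off + take)], wconn)
      flush(wconn)
      chunk <- raw(0)
      while (length(chunk) < take) {
        chunk <- c(chunk, readBin(rconn, "raw", n = take - length(chunk)))
      }
      got <- c(got, chunk)
      off <- off + take
    }
    got
  }
  structure(
    list(
      type = "socket",
      port = port,
      deliver = function(frames) {
        lapply(frames, function(fr) {
          fwd <- fr$from < fr$to
          received <- chunked_send(
            if (fwd) cl else peer,
            if (fwd) peer else cl,
            fr$bytes
          )
          fr$bytes <- received
          fr
        })
      },
      close = function() {
        try(close(cl), silent = TRUE)
        try(close(peer), silent = TRUE)
        invisible(NULL)
      }
    ),
    class = "mpc_transport"
  )
}
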