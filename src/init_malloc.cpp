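#include <Rcpp.h>
#ifdef __GLIBC__
#include <malloc.h>
// Large scratch matrices (im2col buffers, offset-gemm intermediates) are
// allocated and freed on every layer call; keep them on the heap instead of
// mmap so the pages are reused rather than faulted in each time.
static int malloc_tuned = [] {
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
  return 0;
}();
#endif
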