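#ifndef LANSSM_FAST_TANH_H
#define LANSSM_FAST_TANH_H

#include <cstddef>

// In-place vectorized tanh with absolute error < 3e-7 (Pade
// continued-fraction core, exact exponential tail). Compiled with runtime
// dispatch so modern SIMD units are used when available; see fast_tanh.cpp.
void lanssm_tanh_array(double *p, std::size_t n);

#endif
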