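CXX_STD = CXX17
PKG_CPPFLAGS = -I.
PKG_LIBS = $(LAPACK_LIBS) $(BLAS_LIBS) $(FLIBS)
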