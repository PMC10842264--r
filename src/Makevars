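# FFTW (double + single precision) from the same prefix that R lives in.
PKG_CPPFLAGS = -I$(R_HOME)/../../include
PKG_LIBS = -L$(R_HOME)/../../lib -lfftw3 -lfftw3f
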