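# Reduced-domain topology grammar for desk-scale runs: small kernel counts
# and unit counts so that proxy evaluation and full training stay cheap on
# one CPU. Same surface language as the full grammar.
<network> ::= <input> <learning> <convblock> <denseblock>
<input> ::= B=<B> w=<w> wstep=<wstep>
<learning> ::= f=<f> eta=<eta>
<B> ::= 16 | 32
<w> ::= 16 | 24
<wstep> ::= 2
<f> ::= Adam | RMSProp
<eta> ::= 0.01 | 0.003
<convblock> ::= <conv1> | <conv1> <conv2>
<conv1> ::= ck1=<ck> cs1=<cs> cp1=<cp> ca1=<ca>
<conv2> ::= ck2=<ck> cs2=<cs> cp2=<cp> ca2=<ca>
<ck> ::= 4 | 8
<cs> ::= 3
<cp> ::= 1 | 2
<ca> ::= linear | ReLU
<denseblock> ::= <dense1>
<dense1> ::= dt1=<dt> dn1=<dn> dd1=<dd> da1=<da> dr1=<dr>
<dt> ::= feedforward | LSTM | GRU
<dn> ::= 8 | 16
<dd> ::= 0
<da> ::= linear | ReLU
<dr> ::= none
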