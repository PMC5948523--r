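# Network-topology grammar (Backus-Naur Form).
# One rule per line: <nonterminal> ::= alternative | alternative
# Terminal text is kept verbatim, so the generated sentence is the
# key=value phenotype description consumed by parse_phenotype_text().
<network> ::= <input> <learning> <convblock> <denseblock>
<input> ::= B=<B> w=<w> wstep=<wstep>
<learning> ::= f=<f> eta=<eta>
<B> ::= 25 | 50 | 100
<w> ::= 8 | 16 | 24 | 32
<wstep> ::= 1 | 2 | 4
<f> ::= SGD | AdaGrad | AdaDelta | RMSProp | Adam | Adamax
<eta> ::= 0.001 | 0.0005 | 0.0001
<convblock> ::= <conv1> | <conv1> <conv2> | <conv1> <conv2> <conv3> | <conv1> <conv2> <conv3> <conv4> | <conv1> <conv2> <conv3> <conv4> <conv5>
<conv1> ::= ck1=<ck> cs1=<cs> cp1=<cp> ca1=<ca>
<conv2> ::= ck2=<ck> cs2=<cs> cp2=<cp> ca2=<ca>
<conv3> ::= ck3=<ck> cs3=<cs> cp3=<cp> ca3=<ca>
<conv4> ::= ck4=<ck> cs4=<cs> cp4=<cp> ca4=<ca>
<conv5> ::= ck5=<ck> cs5=<cs> cp5=<cp> ca5=<ca>
<ck> ::= 8 | 16 | 32 | 64 | 128 | 256
<cs> ::= 2 | 3 | 4
<cp> ::= 1 | 2 | 3
<ca> ::= linear | ReLU
<denseblock> ::= <dense1> | <dense1> <dense2> | <dense1> <dense2> <dense3>
<dense1> ::= dt1=<dt> dn1=<dn> dd1=<dd> da1=<da> dr1=<dr>
<dense2> ::= dt2=<dt> dn2=<dn> dd2=<dd> da2=<da> dr2=<dr>
<dense3> ::= dt3=<dt> dn3=<dn> dd3=<dd> da3=<da> dr3=<dr>
<dt> ::= feedforward | LSTM | GRU
<dn> ::= 128 | 256 | 512 | 1024
<dd> ::= 0 | 0.25 | 0.5
<da> ::= linear | ReLU
<dr> ::= none | L1 | L2
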