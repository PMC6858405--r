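((sp04:0.006562671541,sp01:0.006562671541):0.9934373285,((((((sp02:0.04399596978,sp26:0.04399596978):0.2641145071,sp24:0.3081104768):0.01267844713,(sp23:0.2621280472,(sp06:0.2394528335,sp32:0.2394528335):0.02267521372):0.05866087674):0.01530861686,sp08:0.3360975408):0.04248746988,((sp14:0.04931124071,sp29:0.04931124071):0.1707151825,sp07:0.2200264232):0.1585585875):0.2137831209,(((((sp03:0.1250838154,(sp25:0.02446748398,sp13:0.02446748398):0.1006163314):0.1190672836,sp27:0.244151099):0.1113805797,sp33:0.3555316787):0.08154877781,((sp34:0.2519999665,((sp05:0.1150826408,sp16:0.1150826408):0.04638026942,(sp19:0.1541935959,sp11:0.1541935959):0.007269314372):0.09053705626):0.1638190858,((sp17:0.2170199,sp18:0.2170199):0.01128924384,((sp12:0.06667064934,(sp21:0.02685178757,sp31:0.02685178757):0.03981886178):0.05067494167,sp22:0.117345591):0.1109635528):0.1875099084):0.02126140418):0.00112895074,(((sp20:0.05199509736,sp30:0.05199509736):0.2912738562,(sp28:0.2146325241,sp15:0.2146325241):0.1286364294):0.08661385386,(sp10:0.409498419,sp09:0.409498419):0.02038438834):0.008326599836):0.1541587244):0.4076318684);
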