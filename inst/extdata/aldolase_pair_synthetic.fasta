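>ALDOB_SYN synthetic stand-in, fructose-bisphosphate aldolase B type (364 aa)
GAAAGNSKMQAQMALGVFNKMNNFNFESGMKTFTAGNMKGTDFANEKAFASTVDSAGKTF
NMANLIENDKTQSALSKTMIMNAKFTSMMASKGMNAQTGEFASKMSMFMSGIMAKAMLST
AATNKNSFVMFALFKSATGAFIKANDFSWNKQFQNSNEKMSTFWGGDFAKIIGSAEKMNS
WDSAEAFLMKSMNIASNNAMTMKVALNGANDQKEIITGAVGSSSKIVDGQMTSEKDTEGA
INKYTPLEVAMATVTALRRGTMTTMSMTKSGQFDSMKGFNGAGTSNMKEDINQTNKMIVG
IVERALQASALSAWKGQAANEEDESVAVWNTTDKEMDSMFKAEINLSTIIDKWVFEDASS
RSFG
>ALDOC_SYN synthetic stand-in, fructose-bisphosphate aldolase C type (363 aa)
GHAAGNSKMQAQAALGFFNKMNNFNLEIGFKQFGAGHMKIEDFEAEKMFASTVGSNGKTV
NMAHLIGNDKEQHGLGKTMEMGQKFFSMMNGKGMNAQTGEQASKMSMFHSGGMAKNTLST
AATNKISSGNEALNKGALGAFIKLNDFSWNKQFQNSNEKMSTSWGGDEAKIGESANKMGT
WDSATAFLHKGQNINSNAAETMKVAMNGANDQKVGITGIVGSSGKFVDGQEEIMKDTEGA
INKFSNQIVAMATVTALRRHTMTTMSMTKSGQFDSSKEFSGAGTENMKEDIGGTNKMLEH
IVERALQASALSAWRGVKENEKDESVHVWNTTIKEMESEFKEEINESTIIHKWVNEDASS
RSF
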