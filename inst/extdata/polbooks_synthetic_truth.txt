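b001 b002 b003 b004 b005 b006 b007 b008 b009 b010 b011 b012 b013 b014 b015 b016 b017 b018 b019 b020 b021 b022 b023 b024 b025 b026 b027 b028 b029 b030 b031 b032 b033 b034 b035 b036 b037 b038 b039 b040 b041 b042 b043 b044 b045 b046 b047 b048 b049
b050 b051 b052 b053 b054 b055 b056 b057 b058 b059 b060 b061 b062 b063 b064 b065 b066 b067 b068 b069 b070 b071 b072 b073 b074 b075 b076 b077 b078 b079 b080 b081 b082 b083 b084 b085 b086 b087 b088 b089 b090 b091 b092
b093 b094 b095 b096 b097 b098 b099 b100 b101 b102 b103 b104 b105
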